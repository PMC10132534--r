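test_that("scenario files round-trip field-by-field in YAML and JSON", {
  for (ext in c(".yaml", ".json")) {
    cfg <- builtin_scenario("IP100")
    p <- tempfile(fileext = ext)
    write_scenario(cfg, p)
    cfg2 <- load_scenario(p)
    expect_equal(cfg, cfg2)
    unlink(p)
  }
})

test_that("invariant violations are rejected with informative errors", {
  cfg <- builtin_scenario("IP100")
  # proportions not summing to 1 (shrink the largest pathway share)
  bad <- cfg
  i_da <- which(vapply(bad$pathways, `[[`, character(1), "name") == "DA")
  bad$pathways[[i_da]]$proportion <- bad$pathways[[i_da]]$proportion - 0.1
  expect_error(validate_scenario(bad), "sum to")
  # malformed distribution in a scenario file
  p <- tempfile(fileext = ".yaml")
  write_scenario(cfg, p)
  txt <- readLines(p)
  txt <- sub("min: 730.5", "min: 99999", txt, fixed = TRUE)
  writeLines(txt, p)
  expect_error(load_scenario(p), "min <= mode|min < max")
  unlink(p)
  # missing schedule for a housing-using pathway
  bad <- cfg
  bad$policy$schedules[["DA"]] <- NULL
  expect_error(validate_scenario(bad), "DA")
  # occupancy above capacity
  expect_error(
    initial_state(capacity = c(shelter = 5, All = 3),
                  occupied = c(shelter = 0, All = 4),
                  queue = c(All = 0), shelter_mix = c(All = 0)),
    "exceeds capacity")
  expect_error(load_scenario(tempfile(fileext = ".yaml")), "no such file")
})

test_that("all built-in scenarios validate and proportions sum to one", {
  for (nm in c("aggregate_plan", "aggregate_70pct", "IP100", "IP90", "IP80",
               "IP1080", "IP0590", "micro_worked_example")) {
    cfg <- builtin_scenario(nm)
    expect_silent(validate_scenario(cfg))
    props <- vapply(cfg$pathways, `[[`, numeric(1), "proportion")
    expect_equal(sum(props), 1)
  }
  expect_equal(length(builtin_scenario("IP100")$pathways), 8L)
  expect_error(builtin_scenario("IP95"), "unknown scenario")
  expect_error(builtin_policy("nope"), "unknown policy")
})

test_that("built-in anchor tables match the published plans cell-for-cell", {
  # aggregate plan: units at the beginning of each year
  agg <- builtin_policy("aggregate_plan")
  expect_equal(agg$schedules$shelter$units,
               c(1500L, 2500L, 3200L, 3000L, 1600L, 1200L))
  expect_equal(agg$schedules$housing$units,
               c(4000L, 6000L, 9600L, 13600L, 19300L, 24000L))
  expect_equal(format(agg$schedules$housing$dates[3]), "2024-01-01")

  # detailed baseline: units by the end of each year
  ip <- builtin_policy("IP100")
  expected <- list(
    shelter = c(2652, 3221, 2984, 1652, 1253),
    Youth = c(104, 121, 138, 195, 173),
    `RR-Long` = c(677, 1459, 2260, 3416, 4368),
    `RR-Short` = c(130, 152, 173, 244, 216),
    RRH = c(1120, 1305, 1488, 2100, 1857),
    DA = c(1459, 3085, 4869, 7359, 9411),
    PSH = c(3351, 4054, 4837, 6013, 6914),
    `PSH-Seniors` = c(521, 1086, 1691, 2532, 3194)
  )
  for (nm in names(expected))
    expect_equal(ip$schedules[[nm]]$units, as.integer(expected[[nm]]),
                 label = nm)
  expect_equal(format(ip$schedules$DA$dates[5]), "2027-12-31")
  # end-of-2027 DA anchor
  expect_equal(ip$schedules$DA$units[5], 9411L)
})

test_that("the 70%-housing aggregate variant scales housing and never cuts shelter", {
  pol <- builtin_policy("aggregate_70pct")
  plan <- builtin_policy("aggregate_plan")
  expect_equal(pol$schedules$housing$units,
               as.integer(floor(0.70 * plan$schedules$housing$units + 0.5)))
  expect_true(all(diff(pol$schedules$shelter$units) >= 0))
})

test_that("scale_policy applies factors with half-up rounding and records provenance", {
  ip100 <- builtin_policy("IP100")
  ip1080 <- builtin_policy("IP1080")
  # DA end-of-2027: 1.10 x 9,411 = 10,352.1 -> 10,352
  expect_equal(ip1080$schedules$DA$units[5], 10352L)
  expect_equal(ip1080$schedules$shelter$units, ip100$schedules$shelter$units)
  expect_equal(ip1080$schedules$Youth$units,
               as.integer(floor(0.80 * ip100$schedules$Youth$units + 0.5)))
  ip90 <- builtin_policy("IP90")
  # RR-Long end-of-2027: 0.9 x 4,368 = 3,931.2 -> 3,931
  expect_equal(ip90$schedules$`RR-Long`$units[5], 3931L)
  expect_match(ip90$provenance, "scaled from IP100")
  # identity factors leave the policy unchanged
  same <- scale_policy(ip100, 1, names(ip100$schedules))
  for (nm in names(ip100$schedules))
    expect_equal(same$schedules[[nm]]$units, ip100$schedules[[nm]]$units)
  expect_error(scale_policy(ip100, 1.1, "DA", 0.8, "DA"), "disjoint")
  expect_error(scale_policy(ip100, 1.1, "NoSuchResource"), "unknown resource")
})

test_that("reciprocal scalings compose back to the base within one unit", {
  ip100 <- builtin_policy("IP100")
  all_res <- names(ip100$schedules)
  there <- scale_policy(ip100, 0.8, all_res)
  back <- scale_policy(there, 1 / 0.8, all_res)
  for (nm in all_res)
    expect_true(all(abs(back$schedules[[nm]]$units -
                          ip100$schedules[[nm]]$units) <= 1), label = nm)
})

test_that("arrival rates compound year-over-year and hold after the last factor", {
  sp <- arrival_spec(10, "2022-01-01",
                     c("2022" = 1.2, "2023" = 1.1, "2024" = 1.0,
                       "2025" = 0.9, "2026" = 0.9))
  expect_equal(arrival_rate_on(sp, "2022-06-15"), 12)
  expect_equal(arrival_rate_on(sp, "2026-03-01"),
               10 * 1.2 * 1.1 * 1.0 * 0.9 * 0.9)  # 10.692
  expect_equal(arrival_rate_on(sp, "2030-01-01"), 10.692)
  expect_error(arrival_rate_on(sp, "2021-12-31"), "precedes")
  flat <- arrival_spec(10, "2022-01-01", c("2022" = 1, "2023" = 1))
  expect_equal(arrival_rate_on(flat, "2023-06-01"), 10)
  # base-relative alternative: each factor applies to the base rate
  sp2 <- arrival_spec(10, "2022-01-01", c("2022" = 1.2, "2023" = 1.1),
                      compounding = FALSE)
  expect_equal(arrival_rate_on(sp2, "2023-06-01"), 11)
  expect_equal(arrival_rate_on(sp2, "2025-06-01"), 11)
})
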