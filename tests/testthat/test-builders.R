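test_that("the aggregate model wires one pathway with the published housing law", {
  cfg <- build_aggregate(builtin_policy("aggregate_plan"))
  expect_equal(length(cfg$pathways), 1L)
  expect_equal(cfg$pathways[[1]]$proportion, 1)
  expect_equal(cfg$pathways[[1]]$shelter_policy, "until_housing")
  ht <- cfg$pathways[[1]]$housing_time
  expect_equal(ht$kind, "triangular")
  expect_equal(unlist(ht$params), c(min = 0, mode = 6 * 365.25,
                                    max = 8 * 365.25))
  # about 52% of occupants leave within five years under this law
  expect_equal(triangular_cdf(5, 0, 6, 8), 25 / 48)
  # housing anchor at the beginning of 2024
  s <- cfg$policy$schedules[["All"]]
  expect_equal(s$units[format(s$dates) == "2024-01-01"], 9600L)
  expect_equal(format(cfg$horizon), c("2022-01-01", "2027-12-31"))
  expect_error(build_aggregate(builtin_policy("IP100")), "housing")
})

test_that("the detailed model wires the eight published pathways", {
  cfg <- build_detailed(builtin_policy("IP100"))
  nms <- vapply(cfg$pathways, `[[`, character(1), "name")
  expect_setequal(nms, c("Youth", "RR-Long", "RR-Short", "RRH", "SR", "DA",
                         "PSH", "PSH-Seniors"))
  get <- function(nm) cfg$pathways[[which(nms == nm)]]
  y <- get("Youth")
  expect_equal(y$shelter_policy, "none")
  expect_equal(y$housing_time$kind, "uniform")
  expect_equal(unlist(y$housing_time$params), c(min = 365.25, max = 730.5))
  expect_equal(get("RR-Short")$housing_time$kind, "fixed")
  expect_equal(get("RR-Short")$housing_time$params$value, 91)
  expect_equal(get("SR")$shelter_stay$params$value, 152)
  expect_false(get("SR")$uses_housing)
  # shelter priorities: PSH classes first, then DA, RRH, SR
  pr <- vapply(cfg$pathways, `[[`, integer(1), "priority")
  names(pr) <- nms
  expect_true(pr[["PSH"]] == pr[["PSH-Seniors"]])
  expect_true(pr[["PSH"]] < pr[["DA"]] && pr[["DA"]] < pr[["RRH"]] &&
                pr[["RRH"]] < pr[["SR"]])
  # 2025 housing anchors across the seven housing resources
  tot <- sum(vapply(setdiff(names(cfg$policy$schedules), "shelter"),
                    function(nm) {
                      s <- cfg$policy$schedules[[nm]]
                      s$units[format(s$dates) == "2025-12-31"]
                    }, integer(1)))
  expect_equal(tot, 15456L)
  expect_equal(format(cfg$horizon), c("2023-01-01", "2028-12-31"))
  pol <- builtin_policy("IP100")
  pol$schedules[["RRH"]] <- NULL
  expect_error(build_detailed(pol), "RRH")
})

test_that("the default initial state rescales the 2023 plan to the aggregate totals", {
  ini <- default_initial_state("detailed", builtin_policy("IP100"), q0 = 1000)
  housing <- ini$capacity[setdiff(names(ini$capacity), "shelter")]
  expect_equal(sum(housing), 6000L)
  expect_equal(ini$capacity[["shelter"]], 2500L)
  # rescale factor 6000/7362 applied to the end-of-2023 anchors
  anchors <- c(Youth = 104, `RR-Long` = 677, `RR-Short` = 130, RRH = 1120,
               DA = 1459, PSH = 3351, `PSH-Seniors` = 521)
  expect_equal(sum(anchors), 7362)
  expect_true(all(abs(housing[names(anchors)] -
                        anchors * 6000 / 7362) <= 1))
  # fully occupied, queue apportioned by arrival shares
  expect_equal(ini$occupied, ini$capacity)
  expect_equal(sum(ini$queue), 1000L)
  expect_equal(sum(ini$shelter_mix), 2500L)
  # no initial shelter occupants on pathways that never use shelter
  expect_equal(unname(ini$shelter_mix[c("Youth", "RR-Long", "RR-Short")]),
               rep(0L, 3))
  agg <- default_initial_state("aggregate", q0 = 500)
  expect_equal(agg$capacity, c(shelter = 1500L, housing = 4000L))
  expect_equal(sum(agg$queue), 500L)
})

test_that("with an empty initial queue, unmet need at t = 0 is the sheltered count", {
  cfg <- builtin_scenario("IP100", q0 = 0)
  tr <- run_replication(cfg, 1, keep_persons = FALSE)
  expect_equal(sum(unmet_need(tr, 0)), 2500)
  expect_equal(sum(tr$queued[1, ]), 0)
})

test_that("routing: no fixed-stay person in housing, no direct pathway in shelter", {
  cfg <- builtin_scenario("IP100")
  tr <- run_replication(cfg, 1)
  p <- tr$persons
  expect_true(all(is.na(p$housing_entry[p$pathway == "SR"])))
  direct <- p$pathway %in% c("Youth", "RR-Long", "RR-Short")
  expect_true(all(is.na(p$shelter_entry[direct])))
})

test_that("end-of-2023 unmet need is monotone in the initial queue and brackets the anchor", {
  means <- vapply(c(0, 3000, 8000), function(q0) {
    cfg <- builtin_scenario("IP100", q0 = q0)
    res <- run_scenario(cfg, reps = 5, keep_persons = FALSE)
    mean(vapply(res$traces,
                function(tr) sum(unmet_need(tr, "2023-12-31")), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], 7125)  # q0 = 0 sits strictly below the anchor
  expect_error(calibrate_q0(target = 7125, reps = 2, bounds = c(0, 10)),
               "widen")
})
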