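test_that("the worked micro-example reproduces the hand event-walk", {
  cfg <- builtin_scenario("micro_worked_example")
  tr <- run_replication(cfg, 1, record_events = TRUE)
  at <- function(t, what) {
    i <- which(tr$times == t)
    switch(what, housed = sum(tr$housing_occupied[i, ]),
           sheltered = sum(tr$sheltered[i, ]), queued = sum(tr$queued[i, ]))
  }
  # t = 3: person 1 housed, person 2 sheltered (blocked), person 3 queued
  expect_equal(at(3, "housed"), 1)
  expect_equal(at(3, "sheltered"), 1)
  expect_equal(at(3, "queued"), 1)
  expect_equal(sum(unmet_need(tr, 3)), 2)
  # t = 10: person 1 exits, person 2 housed, person 3 sheltered
  expect_equal(at(10, "housed"), 1)
  expect_equal(at(10, "sheltered"), 1)
  expect_equal(at(10, "queued"), 0)
  p <- tr$persons
  expect_equal(p$arrival, c(0, 1, 2))
  expect_equal(p$housing_entry, c(0, 10, 20))
  expect_equal(p$exit, c(10, 20, 30))
  # person 2 spent 9 days in shelter (entered t = 1, left t = 10)
  expect_equal(p$shelter_exit[2] - p$shelter_entry[2], 9)
  # person 2 was housed at the instant person 1's unit freed, never earlier
  ev <- tr$events
  admit2 <- ev[ev$kind == "housing_admit" & ev$person == 2, ]
  expect_equal(admit2$time, 10)
})

test_that("replications are deterministic in (config, seed, rep)", {
  cfg <- random_scenario(42)
  a <- run_replication(cfg, 2, record_events = TRUE)
  b <- run_replication(cfg, 2, record_events = TRUE)
  expect_identical(a, b)
  c <- run_replication(cfg, 3)
  expect_false(identical(a$queued, c$queued))
  cfg2 <- cfg
  cfg2$master_seed <- cfg$master_seed + 1L
  d <- run_replication(cfg2, 2)
  expect_false(identical(a$persons$arrival, d$persons$arrival))
})

test_that("conservation, capacity bounds and blocking hold on randomized scenarios", {
  for (seed in 1:10) {
    cfg <- random_scenario(seed)
    tr <- run_replication(cfg, 1, record_events = TRUE)
    # cumulative arrivals (incl. returns) = queued + sheltered + housed + exits
    expect_equal(conservation_gap(tr), 0, label = paste("seed", seed))
    # occupancy never exceeds active units (engine also hard-checks this)
    ev <- tr$events
    adm <- ev[ev$kind %in% c("housing_admit", "shelter_admit", "capacity_change"), ]
    expect_true(all(adm$occupied_after <= adm$active_after),
                label = paste("seed", seed))
    # blocking audit: every housing admission happened into a free unit
    ha <- ev[ev$kind == "housing_admit", ]
    expect_true(all(ha$occupied_after >= 1 &
                      ha$occupied_after <= ha$active_after))
  }
})

test_that("degenerate systems behave exactly", {
  # no arrivals, empty initial state: identically zero series
  cfg <- simple_scenario(arrive_at = numeric(0), shelter_cap = 2L,
                         housing_cap = 2L)
  tr <- run_replication(cfg, 1)
  expect_true(all(tr$queued == 0) && all(tr$sheltered == 0) &&
                all(tr$housing_occupied == 0))
  # zero capacity everywhere: final queue equals total arrivals
  cfg <- simple_scenario(arrive_at = c(1, 2, 5, 7, 20), shelter_cap = 0L,
                         housing_cap = 0L)
  tr <- run_replication(cfg, 1)
  n <- length(tr$times)
  expect_equal(sum(tr$queued[n, ]), 5)
  expect_equal(as.numeric(tr$cum_exits[n]), 0)
})

test_that("capacity decreases retire units on vacancy without evicting", {
  # 8 units occupied by 8 people (20-day stays), 3 waiting; target drops to 5
  cfg <- simple_scenario(arrive_at = numeric(0), shelter_cap = 0L,
                         housing_cap = 8L, housing_days = 20,
                         housing_anchors = list(day = 10, units = 5L),
                         initial_occupied_housing = 8L, initial_queue = 3L,
                         horizon_days = 40)
  tr <- run_replication(cfg, 1, record_events = TRUE)
  # after the cut nobody is evicted: occupancy stays 8 until the stays end
  i15 <- which(tr$times == 15)
  expect_equal(as.numeric(tr$housing_occupied[i15, ]), 8)
  # at t = 20 all 8 exit; 3 vacancies retire, then waiters fill 3 of 5 units
  i25 <- which(tr$times == 25)
  expect_equal(as.numeric(tr$housing_occupied[i25, ]), 3)
  ha <- tr$events[tr$events$kind == "housing_admit", ]
  expect_true(all(ha$active_after[ha$time >= 20] == 5))
  # increase with waiters admits immediately
  cfg2 <- simple_scenario(arrive_at = c(0, 0.5, 1), shelter_cap = 0L,
                          housing_cap = 0L, housing_days = 50,
                          housing_anchors = list(day = 10, units = 5L),
                          horizon_days = 30)
  tr2 <- run_replication(cfg2, 1, record_events = TRUE)
  ha2 <- tr2$events[tr2$events$kind == "housing_admit", ]
  expect_equal(ha2$time, c(10, 10, 10))
})

test_that("shelter admits by priority rank, FIFO within rank", {
  start <- as.Date("2023-01-01")
  pw <- list(
    pathway_spec("PSHlike", 0.5, "until_housing",
                 housing_time = dist_fixed(500), priority = 1L),
    pathway_spec("RRHlike", 0.5, "until_housing",
                 housing_time = dist_fixed(500), priority = 3L)
  )
  pol <- investment_policy("prio", list(
    capacity_schedule("shelter", c(start, start + 10, start + 20),
                      c(0L, 1L, 2L), interpolation = "step"),
    capacity_schedule("PSHlike", start, 0L, interpolation = "step"),
    capacity_schedule("RRHlike", start, 0L, interpolation = "step")
  ))
  ini <- initial_state(c(shelter = 0L, PSHlike = 0L, RRHlike = 0L),
                       c(shelter = 0L, PSHlike = 0L, RRHlike = 0L),
                       c(PSHlike = 0L, RRHlike = 0L),
                       c(PSHlike = 0L, RRHlike = 0L))
  cfg <- scenario_config(
    model = "detailed", pathways = pw,
    arrivals = arrival_spec(1, start,
                            fixed = list(times = c(0, 5),
                                         pathways = c(2L, 1L))),
    returns = return_spec(0, dist_fixed(1)), policy = pol, initial = ini,
    horizon = c(start, start + 30), sample_interval_days = 1,
    replications = 1L, master_seed = 1L)
  tr <- run_replication(cfg, 1)
  p <- tr$persons
  # rank 1 (arrived t=5) admitted at the first unit, rank 3 at the second
  expect_equal(p$shelter_entry[p$pathway == "PSHlike"], 10)
  expect_equal(p$shelter_entry[p$pathway == "RRHlike"], 20)
  # equal ranks: FIFO by arrival
  pw2 <- list(
    pathway_spec("A", 0.5, "until_housing", housing_time = dist_fixed(500),
                 priority = 2L),
    pathway_spec("B", 0.5, "until_housing", housing_time = dist_fixed(500),
                 priority = 2L)
  )
  pol2 <- investment_policy("fifo", list(
    capacity_schedule("shelter", c(start, start + 10), c(0L, 1L),
                      interpolation = "step"),
    capacity_schedule("A", start, 0L, interpolation = "step"),
    capacity_schedule("B", start, 0L, interpolation = "step")
  ))
  ini2 <- initial_state(c(shelter = 0L, A = 0L, B = 0L),
                        c(shelter = 0L, A = 0L, B = 0L),
                        c(A = 0L, B = 0L), c(A = 0L, B = 0L))
  cfg2 <- scenario_config(
    model = "detailed", pathways = pw2,
    arrivals = arrival_spec(1, start,
                            fixed = list(times = c(0, 4), pathways = c(2L, 1L))),
    returns = return_spec(0, dist_fixed(1)), policy = pol2, initial = ini2,
    horizon = c(start, start + 20), sample_interval_days = 1,
    replications = 1L, master_seed = 1L)
  tr2 <- run_replication(cfg2, 1)
  p2 <- tr2$persons
  expect_equal(p2$shelter_entry[p2$arrival == 0], 10)  # earlier arrival first
  expect_true(is.na(p2$shelter_entry[p2$arrival == 4]))
})

test_that("fixed-stay pathway occupies shelter for its stay then exits", {
  start <- as.Date("2023-01-01")
  pw <- list(pathway_spec("SR", 1, "fixed_stay",
                          shelter_stay = dist_fixed(152), priority = 1L))
  pol <- investment_policy("sr", list(
    capacity_schedule("shelter", start, 1L, interpolation = "step")))
  ini <- initial_state(c(shelter = 1L), c(shelter = 0L), c(SR = 0L),
                       c(SR = 0L))
  cfg <- scenario_config(
    model = "detailed", pathways = pw,
    arrivals = arrival_spec(1, start,
                            fixed = list(times = 3, pathways = 1L)),
    returns = return_spec(0, dist_fixed(1)), policy = pol, initial = ini,
    horizon = c(start, start + 200), sample_interval_days = 1,
    replications = 1L, master_seed = 1L)
  tr <- run_replication(cfg, 1)
  p <- tr$persons
  expect_equal(p$shelter_entry, 3)
  expect_equal(p$exit, 3 + 152)
  expect_equal(p$state, 3)
  expect_true(is.na(p$housing_entry))
})

test_that("arrival streams match the Poisson law and the pathway mix", {
  # constant 10/day over one year: mean count across 200 seeds within 3 SE
  start <- as.Date("2023-01-01")
  cfg <- mmc_scenario(10, 1 / 5, 100L, horizon_days = 365)
  counts <- vapply(1:200, function(i) nrow(generate_arrivals(cfg, i)),
                   numeric(1))
  expect_lt(abs(mean(counts) - 3650), 3 * sqrt(3650 / 200))
  # pathway shares: DA draws about 28% of arrivals
  ip <- builtin_scenario("IP100")
  arr <- do.call(rbind, lapply(1:4, function(i) generate_arrivals(ip, i)))
  n <- nrow(arr)
  frac <- mean(arr$pathway == "DA")
  expect_lt(abs(frac - 0.28), 3 * sqrt(0.28 * 0.72 / n))
  # the engine consumes exactly this stream
  tr <- run_replication(ip, 2)
  ext <- tr$persons[tr$persons$is_return == 0 & tr$persons$arrival > 0, ]
  arr2 <- generate_arrivals(ip, 2)
  expect_equal(ext$arrival, arr2$time)
  expect_equal(ext$pathway, arr2$pathway)
})

test_that("returns re-enter at the configured rate", {
  # short fixed housing stays, ample capacity, immediate return delay:
  # the returner share of exits estimates the return probability
  start <- as.Date("2023-01-01")
  pw <- list(pathway_spec("All", 1, "none", housing_time = dist_fixed(1)))
  pol <- investment_policy("ret", list(
    capacity_schedule("shelter", start, 0L, interpolation = "step"),
    capacity_schedule("All", start, 5000L, interpolation = "step")))
  ini <- initial_state(c(shelter = 0L, All = 5000L),
                       c(shelter = 0L, All = 0L), c(All = 0L), c(All = 0L))
  cfg <- scenario_config(
    model = "aggregate", pathways = pw,
    arrivals = arrival_spec(20, start),
    returns = return_spec(0.17, dist_fixed(0)),
    policy = pol, initial = ini, horizon = c(start, start + 730),
    sample_interval_days = 30, replications = 1L, master_seed = 3L)
  tr <- run_replication(cfg, 1, keep_persons = FALSE)
  n <- length(tr$times)
  exits <- as.numeric(tr$cum_exits[n])
  returns <- as.numeric(tr$cum_returns[n])
  expect_gt(exits, 1e4)
  expect_lt(abs(returns / exits - 0.17), 3 * sqrt(0.17 * 0.83 / exits))
  # probability 0: no returns at all
  cfg0 <- cfg
  cfg0$returns <- return_spec(0, dist_fixed(0))
  tr0 <- run_replication(cfg0, 1, keep_persons = FALSE)
  expect_equal(as.numeric(tr0$cum_returns[length(tr0$times)]), 0)
})

test_that("adding housing units never worsens unmet person-days under CRN", {
  cfg <- builtin_scenario("IP100")
  cfg2 <- cfg
  for (nm in setdiff(names(cfg2$policy$schedules), "shelter"))
    cfg2$policy$schedules[[nm]]$units <-
      cfg2$policy$schedules[[nm]]$units + 1000L
  base <- vapply(1:5, function(i)
    run_replication(cfg, i, keep_persons = FALSE)$int_unmet_persondays,
    numeric(1))
  more <- vapply(1:5, function(i)
    run_replication(cfg2, i, keep_persons = FALSE)$int_unmet_persondays,
    numeric(1))
  expect_true(all(more <= base))
})

test_that("housing admits the earliest waiter whether sheltered or not; the transit rule blocks bypass", {
  # H-person arrives t=0 but priority sends the later G-person into the only
  # shelter unit, so at t=10 H's housing unit frees with H unsheltered
  start <- as.Date("2023-01-01")
  mk <- function(rule) {
    pw <- list(
      pathway_spec("H", 0.5, "until_housing", housing_time = dist_fixed(100),
                   priority = 2L),
      pathway_spec("G", 0.5, "until_housing", housing_time = dist_fixed(100),
                   priority = 1L)
    )
    pol <- investment_policy("rule", list(
      capacity_schedule("shelter", c(start, start + 2), c(0L, 1L),
                        interpolation = "step"),
      capacity_schedule("H", c(start, start + 10), c(0L, 1L),
                        interpolation = "step"),
      capacity_schedule("G", start, 0L, interpolation = "step")
    ))
    ini <- initial_state(c(shelter = 0L, H = 0L, G = 0L),
                         c(shelter = 0L, H = 0L, G = 0L),
                         c(H = 0L, G = 0L), c(H = 0L, G = 0L))
    scenario_config(
      model = "detailed", pathways = pw,
      arrivals = arrival_spec(1, start,
                              fixed = list(times = c(0, 1), pathways = c(1L, 2L))),
      returns = return_spec(0, dist_fixed(1)), policy = pol, initial = ini,
      horizon = c(start, start + 30), sample_interval_days = 1,
      replications = 1L, master_seed = 1L,
      options = list(admission_rule = rule))
  }
  # default rule: the unsheltered earliest H waiter is housed directly
  tr <- run_replication(mk("fifo_overall"), 1)
  p <- tr$persons
  expect_equal(p$shelter_entry[p$pathway == "G"], 2)   # priority 1 gets shelter
  expect_equal(p$housing_entry[p$pathway == "H"], 10)  # housed from the queue
  # strict transit: H cannot bypass shelter, so the unit stays idle while
  # shelter is held by the blocked G waiter
  tr2 <- run_replication(mk("shelter_transit"), 1)
  p2 <- tr2$persons
  expect_true(is.na(p2$housing_entry[p2$pathway == "H"]))
  n <- length(tr2$times)
  expect_equal(as.numeric(tr2$housing_occupied[n, "H"]), 0)
})
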