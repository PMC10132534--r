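# Fixtures built in code: small scenario generators used across test files.

# A randomized small scenario mixing pathway types, capacity ramps (up and
# down), Poisson arrivals and returns; used for property-style invariants.
random_scenario <- function(seed) {
  set.seed(seed)
  start <- as.Date("2023-01-01")
  horizon_days <- sample(200:500, 1)
  kinds <- sample(c("until_housing", "none", "fixed_stay"), 3, replace = TRUE)
  kinds[1] <- "until_housing"  # always at least one blocking pathway
  props <- stats::runif(3)
  props <- props / sum(props)
  props[3] <- 1 - props[1] - props[2]
  pw <- lapply(1:3, function(i) {
    nm <- paste0("P", i)
    switch(kinds[i],
      until_housing = pathway_spec(nm, props[i], "until_housing",
        housing_time = dist_triangular(0, stats::runif(1, 5, 50),
                                       stats::runif(1, 60, 200)),
        priority = sample(1:3, 1)),
      none = pathway_spec(nm, props[i], "none",
        housing_time = dist_uniform(5, stats::runif(1, 10, 100)),
        priority = sample(1:3, 1)),
      fixed_stay = pathway_spec(nm, props[i], "fixed_stay",
        shelter_stay = dist_fixed(sample(5:60, 1)),
        priority = sample(1:3, 1))
    )
  })
  ramp <- function(n0) {
    dates <- start + c(0, sort(sample(30:(horizon_days - 10), 2)))
    capacity_schedule_units <- c(n0, sample(0:30, 2, replace = TRUE))
    list(dates = dates, units = capacity_schedule_units)
  }
  sched <- list()
  sh <- ramp(sample(0:10, 1))
  sched[[1]] <- capacity_schedule("shelter", sh$dates, sh$units,
                                  sample(c("linear", "step"), 1))
  caps <- c(shelter = sh$units[1])
  for (p in pw) {
    if (p$uses_housing) {
      r <- ramp(sample(0:10, 1))
      sched[[length(sched) + 1]] <-
        capacity_schedule(p$name, r$dates, r$units,
                          sample(c("linear", "step"), 1))
      caps[p$name] <- r$units[1]
    }
  }
  queue <- stats::setNames(sample(0:5, 3, replace = TRUE),
                           vapply(pw, `[[`, character(1), "name"))
  shelter_mix <- stats::setNames(rep(0L, 3),
                                 vapply(pw, `[[`, character(1), "name"))
  occupied <- caps * 0L
  scenario_config(
    model = "detailed", pathways = pw,
    arrivals = arrival_spec(stats::runif(1, 0.2, 2), start),
    returns = return_spec(stats::runif(1, 0, 0.4), dist_uniform(0, 100)),
    policy = investment_policy(paste0("rand", seed), sched),
    initial = initial_state(caps, occupied, queue, shelter_mix),
    horizon = c(start, start + horizon_days),
    sample_interval_days = 7, replications = 1L,
    master_seed = seed
  )
}

# deterministic single-pathway scenario with explicit arrivals and capacity
simple_scenario <- function(arrive_at, shelter_cap, housing_cap,
                            housing_days = 10, horizon_days = 40,
                            shelter_anchors = NULL, housing_anchors = NULL,
                            initial_occupied_housing = 0L, initial_queue = 0L,
                            returns = return_spec(0, dist_fixed(1)),
                            residual = "fresh_draw") {
  start <- as.Date("2023-01-01")
  pw <- list(pathway_spec("All", 1, "until_housing",
                          housing_time = dist_fixed(housing_days)))
  mk_sched <- function(nm, cap0, anchors) {
    if (is.null(anchors)) {
      capacity_schedule(nm, start, cap0, interpolation = "step")
    } else {
      capacity_schedule(nm, c(start, start + anchors$day),
                        c(cap0, anchors$units), interpolation = "step")
    }
  }
  pol <- investment_policy("simple", list(
    mk_sched("shelter", shelter_cap, shelter_anchors),
    mk_sched("All", housing_cap, housing_anchors)
  ))
  ini <- initial_state(
    capacity = c(shelter = shelter_cap, All = housing_cap),
    occupied = c(shelter = 0L, All = as.integer(initial_occupied_housing)),
    queue = c(All = as.integer(initial_queue)),
    shelter_mix = c(All = 0L),
    residual_time_rule = residual
  )
  scenario_config(
    model = "aggregate", pathways = pw,
    arrivals = arrival_spec(1, start,
                            fixed = list(times = arrive_at,
                                         pathways = rep(1L, length(arrive_at)))),
    returns = returns, policy = pol, initial = ini,
    horizon = c(start, start + horizon_days),
    sample_interval_days = 1, replications = 1L, master_seed = 1L
  )
}

conservation_gap <- function(tr) {
  max(abs(tr$cum_arrivals -
            (rowSums(tr$queued) + rowSums(tr$sheltered) +
               rowSums(tr$housing_occupied) + tr$cum_exits)))
}
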