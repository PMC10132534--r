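# Closed-form and brute-force queueing oracles used to validate the engine
# independently of any calibrated scenario.  The full system (tandem
# blocking, priorities, time-varying capacity) has no tractable analytic
# form, so these oracles are applied in engineered regimes the formulas do
# cover: stationary M/M/c configurations, Poisson count laws, and the
# triangular service distribution itself.

#' Triangular cumulative distribution function
#'
#' Piecewise-quadratic closed form. For `x <= mode`:
#' `(x - min)^2 / ((max - min) (mode - min))`.
#'
#' @param x quantile (same units as the parameters).
#' @param min,mode,max triangular parameters, `min <= mode <= max`,
#'   `min < max`.
#' @return probability `P(X <= x)`.
#' @examples
#' # share of housing occupants leaving within 5 years under Tri(0, 6, 8) yr
#' triangular_cdf(5, 0, 6, 8)  # 25/48, about 52%
#' @export
triangular_cdf <- function(x, min, mode, max) {
  if (!(min <= mode && mode <= max && min < max))
    stop("need min <= mode <= max and min < max", call. = FALSE)
  ifelse(x <= min, 0,
  ifelse(x >= max, 1,
  ifelse(x <= mode,
         (x - min)^2 / ((max - min) * (mode - min)),
         1 - (max - x)^2 / ((max - min) * (max - mode)))))
}

#' Erlang-C waiting metrics for the stationary M/M/c queue
#'
#' @param lambda arrival rate.
#' @param mu per-server service rate.
#' @param c number of servers.
#' @return list with `rho` (utilization), `p_wait` (Erlang-C probability of
#'   waiting), `Lq` (mean queue length) and `Wq` (mean wait, `Lq / lambda`).
#' @export
erlang_c <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  if (rho >= 1) stop("unstable: lambda/(c*mu) must be < 1", call. = FALSE)
  # Erlang-B recursion, then the B -> C conversion (numerically stable)
  B <- 1
  for (k in seq_len(c)) B <- a * B / (k + a * B)
  p_wait <- B / (1 - rho * (1 - B))
  Lq <- p_wait * rho / (1 - rho)
  list(rho = rho, p_wait = p_wait, Lq = Lq, Wq = Lq / lambda)
}

#' Brute-force M/M/c mean queue length via a truncated birth-death chain
#'
#' Independent numerical cross-check of [erlang_c()]: solves the stationary
#' distribution of the M/M/c birth-death chain truncated at `n_max` states
#' directly from the balance equations.
#'
#' @inheritParams erlang_c
#' @param n_max truncation level (states 0..n_max).
#' @return mean queue length `Lq`.
#' @export
mmc_lq_bruteforce <- function(lambda, mu, c, n_max = 1000L) {
  n <- 0:n_max
  death <- pmin(n, c) * mu
  # unnormalized pi via detailed balance: pi_n = pi_{n-1} * lambda / death_n
  logpi <- cumsum(c(0, log(lambda) - log(death[-1])))
  logpi <- logpi - max(logpi)
  pi <- exp(logpi) / sum(exp(logpi))
  sum(pmax(n - c, 0) * pi)
}

#' Little's-law residual of a simulated trace
#'
#' Computes `|L - lambda * W| / L` over a time window, where `L` is the
#' time-average number in the subsystem (from the sampled series), `lambda`
#' the observed departure throughput, and `W` the mean sojourn of the stays
#' completed in the window. For a stationary subsystem the residual
#' converges to 0 as the window grows.
#'
#' @param trace a `replication_trace` run with `keep_persons = TRUE`.
#' @param subsystem `"system"` (queue + shelter + housing, sojourn from
#'   arrival to exit) or `"housing"` (housing units only).
#' @param window length-2 numeric, days from horizon start.
#' @return list with `L`, `lambda`, `W`, `residual`.
#' @export
little_law_residual <- function(trace, subsystem = c("system", "housing"),
                                window) {
  subsystem <- match.arg(subsystem)
  t0 <- window[1]; t1 <- window[2]
  in_w <- trace$times >= t0 & trace$times <= t1
  counts <- switch(subsystem,
    system = rowSums(trace$queued) + rowSums(trace$sheltered) +
      rowSums(trace$housing_occupied),
    housing = rowSums(trace$housing_occupied)
  )
  L <- mean(counts[in_w])
  p <- trace$persons
  if (is.null(p)) stop("need persons table", call. = FALSE)
  if (subsystem == "system") {
    done <- !is.na(p$exit) & p$exit >= t0 & p$exit <= t1
    sojourn <- p$exit[done] - p$arrival[done]
  } else {
    done <- !is.na(p$exit) & !is.na(p$housing_entry) & p$exit >= t0 & p$exit <= t1
    sojourn <- p$exit[done] - p$housing_entry[done]
  }
  n_done <- sum(done)
  if (n_done == 0 || L <= 0)
    stop("zero throughput or empty subsystem in window; residual undefined",
         call. = FALSE)
  lambda <- n_done / (t1 - t0)
  W <- mean(sojourn)
  list(L = L, lambda = lambda, W = W,
       residual = abs(L - lambda * W) / L)
}

#' Check simulated yearly arrival counts against the Poisson mean
#'
#' Generates the arrival stream for `n_seeds` replications, counts arrivals
#' per calendar year, and compares the empirical means with the analytic
#' expectation (daily rate times days in the year). Years off by more than
#' three standard errors are flagged.
#'
#' @param config a [scenario_config].
#' @param n_seeds number of replications (>= 30 recommended).
#' @return data.frame per calendar year with `expected`, `mean`, `se`, `z`
#'   and `flag`.
#' @export
nhpp_count_check <- function(config, n_seeds = 100L) {
  day0 <- config$horizon[1]
  counts <- lapply(seq_len(n_seeds), function(i) {
    arr <- generate_arrivals(config, i)
    table(factor(format(arr$date, "%Y")))
  })
  yrs <- sort(unique(unlist(lapply(counts, names))))
  m <- vapply(counts, function(tb) {
    v <- stats::setNames(rep(0, length(yrs)), yrs)
    v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(yrs)))
  if (length(yrs) == 1L) m <- matrix(m, nrow = 1, dimnames = list(yrs, NULL))
  expected <- vapply(yrs, function(y) {
    a <- max(as.Date(paste0(y, "-01-01")), day0)
    b <- min(as.Date(paste0(as.integer(y) + 1, "-01-01")), config$horizon[2])
    days <- as.numeric(b - a)
    # rate is constant within a calendar year
    days * arrival_rate_on(config$arrivals, a)
  }, numeric(1))
  emp_mean <- rowMeans(m)
  se <- apply(m, 1, stats::sd) / sqrt(n_seeds)
  z <- (emp_mean - expected) / ifelse(se > 0, se, 1)
  data.frame(year = as.integer(yrs), expected = expected, mean = emp_mean,
             se = se, z = z, flag = abs(z) > 3)
}

#' Run the full engine-validation oracle suite
#'
#' Places the engine in configurations with known behaviour and reports a
#' pass/fail table: Erlang-C mean queue length for stable M/M/c
#' configurations, the analytic-vs-brute-force Erlang cross-check, yearly
#' Poisson arrival counts, the triangular sampler against its closed-form
#' CDF (Dvoretzky-Kiefer-Wolfowitz band), and a Little's-law residual.
#'
#' @param reps replications per M/M/c configuration.
#' @param quiet suppress the printed report.
#' @return data.frame of check names, measured values, bounds, and pass
#'   flags (invisibly if `quiet = FALSE`).
#' @export
validate_engine <- function(reps = 30L, quiet = FALSE) {
  rows <- list()
  add <- function(check, value, bound, pass) {
    rows[[length(rows) + 1]] <<- data.frame(check = check, value = value,
                                            bound = bound, pass = pass)
  }

  # Erlang-C agreement for stable M/M/c
  for (cc in c(1L, 2L, 5L)) {
    for (rho in c(0.3, 0.7)) {
      mu <- 1 / 10  # mean service 10 days
      lambda <- rho * cc * mu
      oc <- erlang_c(lambda, mu, cc)
      cfg <- mmc_scenario(lambda, mu, cc, horizon_days = 3652)
      lqs <- vapply(seq_len(reps), function(i) {
        tr <- run_replication(cfg, i, keep_persons = FALSE)
        tr$int_queued_persondays / max(tr$times)
      }, numeric(1))
      se <- stats::sd(lqs) / sqrt(reps)
      dev <- abs(mean(lqs) - oc$Lq)
      add(sprintf("erlang_c c=%d rho=%.1f", cc, rho), dev, 3 * se,
          dev <= 3 * se + 1e-9)
    }
  }

  # analytic vs brute-force CTMC
  oc <- erlang_c(1.5, 1, 2)
  bf <- mmc_lq_bruteforce(1.5, 1, 2)
  add("erlang_c vs CTMC (c=2, lambda=1.5, mu=1)", abs(oc$Lq - bf), 1e-6,
      abs(oc$Lq - bf) < 1e-6)

  # NHPP yearly counts on the detailed arrival process
  cfg <- builtin_scenario("IP100")
  nh <- nhpp_count_check(cfg, n_seeds = 50L)
  add("nhpp yearly counts within 3 SE", max(abs(nh$z)), 3, !any(nh$flag))

  # triangular sampler vs closed-form CDF (DKW band)
  n <- 1e5
  draws <- sample_duration(dist_triangular(YEARS(2), YEARS(6), YEARS(8)), n,
                           seed = 42)
  grid <- seq(YEARS(2), YEARS(8), length.out = 10)
  emp <- stats::ecdf(draws)(grid)
  thr <- triangular_cdf(grid, YEARS(2), YEARS(6), YEARS(8))
  dkw <- sqrt(log(2 / 0.001) / (2 * n))
  add("triangular sampler within DKW band", max(abs(emp - thr)), dkw,
      max(abs(emp - thr)) <= dkw)

  # Little's law on a stable M/M/3
  cfg <- mmc_scenario(0.21, 1 / 10, 3L, horizon_days = 3652)
  tr <- run_replication(cfg, 1)
  ll <- little_law_residual(tr, "system", window = c(365, 3652))
  add("little's law residual (M/M/3)", ll$residual, 0.05,
      ll$residual < 0.05)

  out <- do.call(rbind, rows)
  if (!quiet) {
    print(out, row.names = FALSE)
    cat(sprintf("%d/%d checks passed\n", sum(out$pass), nrow(out)))
  }
  invisible(out)
}

#' Engineered M/M/c scenario for oracle validation
#'
#' Single pathway, no shelter use beyond a formal fixed-stay never invoked,
#' exponential service, constant capacity `c`, homogeneous Poisson arrivals
#' at `lambda`, no returns: a textbook M/M/c queue run on the full engine.
#'
#' @param lambda arrivals/day. @param mu service rate/day. @param c servers.
#' @param horizon_days run length.
#' @return a [scenario_config].
#' @export
mmc_scenario <- function(lambda, mu, c, horizon_days = 3652) {
  start <- as.Date("2023-01-01")
  pw <- list(pathway_spec("All", 1, "none",
                          housing_time = dist_exponential(1 / mu)))
  pol <- investment_policy("mmc", list(
    capacity_schedule("shelter", start, 0L, interpolation = "step"),
    capacity_schedule("All", start, as.integer(c), interpolation = "step")
  ))
  ini <- initial_state(capacity = c(shelter = 0L, All = as.integer(c)),
                       occupied = c(shelter = 0L, All = 0L),
                       queue = c(All = 0L), shelter_mix = c(All = 0L))
  scenario_config(
    model = "aggregate", pathways = pw,
    arrivals = arrival_spec(lambda, start),
    returns = return_spec(0, dist_fixed(1)),
    policy = pol, initial = ini,
    horizon = c(start, start + horizon_days),
    sample_interval_days = 30, replications = 1L, master_seed = 7L
  )
}
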