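#' Pathway specification
#'
#' One population segment flowing through the system: its share of arrivals,
#' how it uses emergency shelter, its shelter admission priority, and the law
#' of its housing occupancy time.
#'
#' @param name pathway name; also names the housing resource serving it.
#' @param proportion fraction of arrivals in `[0, 1]`.
#' @param shelter_policy one of `"none"` (goes straight from the queue to
#'   housing), `"until_housing"` (waits in shelter, blocked, until a housing
#'   unit frees), or `"fixed_stay"` (stays a fixed time in shelter, then
#'   leaves the system).
#' @param shelter_stay a [dist_spec] for the stay length; required for (and
#'   only for) `fixed_stay` pathways.
#' @param priority integer shelter priority rank; smaller ranks are admitted
#'   first when shelter space frees.
#' @param housing_time a [dist_spec] for time spent occupying a housing unit,
#'   or `NULL` for pathways that never use housing.
#' @return An object of class `pathway_spec`.
#' @export
pathway_spec <- function(name, proportion,
                         shelter_policy = c("until_housing", "none", "fixed_stay"),
                         shelter_stay = NULL, priority = 1L,
                         housing_time = NULL) {
  shelter_policy <- match.arg(shelter_policy)
  x <- structure(list(
    name = name, proportion = proportion, shelter_policy = shelter_policy,
    shelter_stay = shelter_stay, priority = as.integer(priority),
    housing_time = housing_time, uses_housing = !is.null(housing_time)
  ), class = "pathway_spec")
  validate_pathway(x)
  x
}

validate_pathway <- function(x) {
  err <- function(msg) {
    stop(sprintf("pathway '%s': %s", x$name, msg), call. = FALSE)
  }
  if (x$proportion < 0 || x$proportion > 1) err("proportion must lie in [0, 1]")
  if (!is.null(x$housing_time)) validate_dist(x$housing_time)
  if (!is.null(x$shelter_stay)) validate_dist(x$shelter_stay)
  if (!x$uses_housing && x$shelter_policy != "fixed_stay")
    err("a pathway without housing must have shelter_policy 'fixed_stay'")
  if (x$shelter_policy == "none" && !x$uses_housing)
    err("shelter_policy 'none' requires a housing_time")
  if (x$shelter_policy == "fixed_stay" && is.null(x$shelter_stay))
    err("shelter_policy 'fixed_stay' requires a shelter_stay distribution")
  invisible(x)
}

#' Arrival process specification
#'
#' Arrivals follow a non-homogeneous Poisson process whose rate is constant
#' within each calendar year. By default yearly factors compound
#' year-over-year: the rate in year `y` is `base_rate` times the product of
#' all factors for years `<= y`. With `compounding = FALSE` each factor is
#' applied to the base rate directly. Years beyond the last listed factor
#' hold the last realized rate.
#'
#' @param base_rate persons/day before any yearly factor.
#' @param start_date first day arrivals can occur (ISO date or `Date`).
#' @param year_factors named numeric vector, names are calendar years, values
#'   the year-over-year multiplicative change.
#' @param compounding logical; see Details.
#' @param fixed optional list `list(times =, pathways =)` of deterministic
#'   arrival times (days from horizon start) and 1-based pathway indices,
#'   overriding the Poisson process; used for hand-traceable micro-scenarios.
#' @return An object of class `arrival_spec`.
#' @export
arrival_spec <- function(base_rate, start_date, year_factors = numeric(),
                         compounding = TRUE, fixed = NULL) {
  x <- structure(list(
    base_rate = base_rate, start_date = as.Date(start_date),
    year_factors = year_factors, compounding = isTRUE(compounding),
    fixed = fixed
  ), class = "arrival_spec")
  if (is.null(fixed)) {
    if (!(base_rate > 0)) stop("base_rate must be > 0", call. = FALSE)
  }
  if (length(year_factors) && any(year_factors <= 0))
    stop("year factors must be > 0", call. = FALSE)
  x
}

#' Daily arrival rate on a given date
#'
#' @param spec an [arrival_spec].
#' @param date a date (coercible by `as.Date`).
#' @return persons/day.
#' @examples
#' sp <- arrival_spec(10, "2022-01-01", c("2022" = 1.2, "2023" = 1.1))
#' arrival_rate_on(sp, "2022-06-01")  # 12
#' @export
arrival_rate_on <- function(spec, date) {
  date <- as.Date(date)
  if (date < spec$start_date)
    stop("date precedes the arrival process start_date", call. = FALSE)
  y <- as.integer(format(date, "%Y"))
  f <- spec$year_factors
  if (!length(f)) return(spec$base_rate)
  yrs <- as.integer(names(f))
  if (spec$compounding) {
    spec$base_rate * prod(f[yrs <= y])
  } else {
    # base-relative: apply the factor listed for the year; years past the
    # last listed factor hold that last factor (no further change)
    if (any(yrs <= y)) spec$base_rate * f[[max(which(yrs <= y))]]
    else spec$base_rate
  }
}

#' Return-to-homelessness specification
#'
#' A fraction of people exiting housing re-enter the system after a random
#' delay, as a fresh arrival.
#'
#' @param probability fraction of housing exits that return, in `[0, 1]`.
#' @param delay a [dist_spec] for the delay between exit and return, days.
#' @param reassign_pathway if `TRUE` (default) the returner's pathway is
#'   redrawn from the arrival mix; if `FALSE` the original pathway is kept.
#' @return An object of class `return_spec`.
#' @export
return_spec <- function(probability = 0.17,
                        delay = dist_uniform(0, 730),
                        reassign_pathway = TRUE) {
  if (probability < 0 || probability > 1)
    stop("return probability must lie in [0, 1]", call. = FALSE)
  validate_dist(delay)
  structure(list(probability = probability, delay = delay,
                 reassign_pathway = isTRUE(reassign_pathway)),
            class = "return_spec")
}

#' Capacity schedule for one resource
#'
#' Total units available over time, anchored at calendar dates. Between
#' anchors the capacity is either interpolated linearly in continuous time
#' (realized as unit-by-unit additions or retirements at the instants the
#' interpolant crosses each integer) or held as a step function that jumps at
#' each anchor date.
#'
#' @param resource_name resource the schedule applies to (`"shelter"` or a
#'   pathway name).
#' @param dates anchor dates, strictly increasing.
#' @param units total units at each anchor, non-negative integers.
#' @param interpolation `"linear"` (default) or `"step"`.
#' @return An object of class `capacity_schedule`.
#' @export
capacity_schedule <- function(resource_name, dates, units,
                              interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  dates <- as.Date(dates)
  if (length(dates) != length(units))
    stop("dates and units must have equal length", call. = FALSE)
  if (is.unsorted(dates, strictly = TRUE))
    stop(sprintf("schedule '%s': anchor dates must be strictly increasing",
                 resource_name), call. = FALSE)
  if (any(units < 0) || any(units != round(units)))
    stop(sprintf("schedule '%s': units must be non-negative integers",
                 resource_name), call. = FALSE)
  structure(list(resource_name = resource_name, dates = dates,
                 units = as.integer(round(units)),
                 interpolation = interpolation),
            class = "capacity_schedule")
}

#' Investment policy: capacity schedules for every resource
#'
#' @param name policy name (e.g. `"IP100"`).
#' @param schedules list of [capacity_schedule] objects, one per resource;
#'   must include `"shelter"`.
#' @param provenance optional free-text description of how the policy was
#'   derived (recorded by [scale_policy()]).
#' @return An object of class `investment_policy`.
#' @export
investment_policy <- function(name, schedules, provenance = NULL) {
  nm <- vapply(schedules, function(s) s$resource_name, character(1))
  names(schedules) <- nm
  if (anyDuplicated(nm))
    stop("duplicate resource schedules in policy", call. = FALSE)
  if (!"shelter" %in% nm)
    stop("policy must include a 'shelter' schedule", call. = FALSE)
  structure(list(name = name, schedules = schedules, provenance = provenance),
            class = "investment_policy")
}

#' Initial system state
#'
#' @param capacity named integer vector of units at simulation start
#'   (must include `"shelter"`).
#' @param occupied named integer vector of initially occupied units,
#'   `0 <= occupied <= capacity` elementwise. For shelter the occupants are
#'   split across shelter-using pathways in `shelter_mix`.
#' @param queue named integer vector: initially unsheltered people per
#'   pathway.
#' @param shelter_mix named integer vector: initial shelter occupants per
#'   pathway (must sum to `occupied["shelter"]`).
#' @param residual_time_rule how service times of initially occupied units
#'   are drawn: `"stationary_residual"` (equilibrium residual lifetimes, as
#'   for a system observed mid-operation) or `"fresh_draw"` (full service
#'   times start at t = 0, which freezes turnover of long-stay resources
#'   for the length of the minimum stay).
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(capacity, occupied, queue, shelter_mix,
                          residual_time_rule = c("stationary_residual",
                                                 "fresh_draw")) {
  residual_time_rule <- match.arg(residual_time_rule)
  if (any(occupied < 0) || any(queue < 0) || any(shelter_mix < 0))
    stop("initial counts must be non-negative", call. = FALSE)
  for (nm in names(occupied)) {
    if (!nm %in% names(capacity))
      stop(sprintf("occupied resource '%s' has no capacity entry", nm),
           call. = FALSE)
    if (occupied[[nm]] > capacity[[nm]])
      stop(sprintf("initial occupancy exceeds capacity for '%s'", nm),
           call. = FALSE)
  }
  if (sum(shelter_mix) != occupied[["shelter"]])
    stop("shelter_mix must sum to occupied['shelter']", call. = FALSE)
  structure(list(capacity = capacity, occupied = occupied, queue = queue,
                 shelter_mix = shelter_mix,
                 residual_time_rule = residual_time_rule),
            class = "initial_state")
}

#' Scenario configuration
#'
#' The complete, seedable description of one simulation experiment.
#'
#' @param model `"aggregate"` or `"detailed"` (informational label).
#' @param pathways list of [pathway_spec]; proportions must sum to 1.
#' @param arrivals an [arrival_spec].
#' @param returns a [return_spec].
#' @param policy an [investment_policy].
#' @param initial an [initial_state].
#' @param horizon length-2 date vector `(start, end)`.
#' @param sample_interval_days spacing of the sampled time series, days.
#' @param replications default number of replications for [run_scenario()].
#' @param master_seed integer master seed; all replication streams derive
#'   from it deterministically.
#' @param unit_costs optional named vector of dollars per unit-year, used
#'   only by [policy_cost()].
#' @param options list of behavioural switches: `admission_rule`
#'   (`"fifo_overall"`, the default, lets housing admit the earliest-arrived
#'   waiter whether sheltered or not; `"shelter_first"` prefers sheltered
#'   waiters), and `include_sr_in_unmet` (count fixed-stay pathway occupants
#'   of shelter toward unmet need; default `TRUE`).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(model = c("detailed", "aggregate"),
                            pathways, arrivals, returns, policy, initial,
                            horizon, sample_interval_days = 7,
                            replications = 100L, master_seed = 20230426L,
                            unit_costs = NULL, options = list()) {
  model <- match.arg(model)
  defaults <- list(admission_rule = "fifo_overall", include_sr_in_unmet = TRUE)
  options <- utils::modifyList(defaults, options)
  x <- structure(list(
    model = model, pathways = pathways, arrivals = arrivals,
    returns = returns, policy = policy, initial = initial,
    horizon = as.Date(horizon), sample_interval_days = sample_interval_days,
    replications = as.integer(replications),
    master_seed = as.integer(master_seed),
    unit_costs = unit_costs, options = options
  ), class = "scenario_config")
  validate_scenario(x)
  x
}

#' Validate a scenario configuration
#'
#' Checks every structural invariant: pathway proportions sum to one,
#' housing-using pathways each have exactly one capacity schedule, the
#' shelter schedule is present, the horizon is non-empty, and initial
#' occupancies respect capacities.
#'
#' @param config a [scenario_config].
#' @return the config, invisibly; errors name the offending field and rule.
#' @export
validate_scenario <- function(config) {
  err <- function(msg) stop(sprintf("invalid scenario: %s", msg), call. = FALSE)
  pw <- config$pathways
  if (!length(pw)) err("at least one pathway required")
  for (p in pw) validate_pathway(p)
  props <- vapply(pw, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    err(sprintf("pathway proportions sum to %.6f, not 1", sum(props)))
  nms <- vapply(pw, `[[`, character(1), "name")
  if (anyDuplicated(nms)) err("duplicate pathway names")
  if (length(config$horizon) != 2 || config$horizon[1] >= config$horizon[2])
    err("horizon start must precede horizon end")
  if (config$replications < 1) err("replications must be >= 1")
  if (!(config$sample_interval_days > 0))
    err("sample_interval_days must be > 0")
  # policy coverage: one schedule per housing-using pathway + shelter
  sched <- config$policy$schedules
  for (p in pw) {
    if (p$uses_housing && !p$name %in% names(sched))
      err(sprintf("no capacity schedule for housing-using pathway '%s'",
                  p$name))
  }
  for (nm in setdiff(names(sched), "shelter")) {
    if (!nm %in% nms)
      err(sprintf("policy schedules resource '%s' but no such pathway exists",
                  nm))
  }
  # initial state coverage
  init <- config$initial
  for (p in pw) {
    if (p$uses_housing && !p$name %in% names(init$capacity))
      err(sprintf("initial state missing capacity for '%s'", p$name))
  }
  bad_q <- setdiff(names(init$queue), nms)
  if (length(bad_q))
    err(sprintf("initial queue names unknown pathway '%s'", bad_q[1]))
  bad_m <- setdiff(names(init$shelter_mix)[init$shelter_mix > 0],
                   nms[vapply(pw, function(p) p$shelter_policy != "none",
                              logical(1))])
  if (length(bad_m))
    err(sprintf("initial shelter occupants assigned to pathway '%s' which does not use shelter",
                bad_m[1]))
  invisible(config)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s model, %d pathway(s), policy '%s'\n",
              x$model, length(x$pathways), x$policy$name))
  cat(sprintf("  horizon %s to %s; %d replications; master seed %d\n",
              format(x$horizon[1]), format(x$horizon[2]),
              x$replications, x$master_seed))
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

scenario_to_list <- function(config) {
  list(
    model = config$model,
    pathways = lapply(config$pathways, function(p) {
      out <- list(name = p$name, proportion = p$proportion,
                  shelter_policy = p$shelter_policy, priority = p$priority)
      if (!is.null(p$shelter_stay)) out$shelter_stay <- dist_to_list(p$shelter_stay)
      if (!is.null(p$housing_time)) out$housing_time <- dist_to_list(p$housing_time)
      out
    }),
    arrivals = list(
      base_rate = config$arrivals$base_rate,
      start_date = format(config$arrivals$start_date),
      year_factors = as.list(config$arrivals$year_factors),
      compounding = config$arrivals$compounding,
      fixed = config$arrivals$fixed
    ),
    returns = list(
      probability = config$returns$probability,
      delay = dist_to_list(config$returns$delay),
      reassign_pathway = config$returns$reassign_pathway
    ),
    policy = list(
      name = config$policy$name,
      provenance = config$policy$provenance,
      schedules = lapply(unname(config$policy$schedules), function(s) {
        list(resource = s$resource_name, dates = format(s$dates),
             units = s$units, interpolation = s$interpolation)
      })
    ),
    initial = list(
      capacity = as.list(config$initial$capacity),
      occupied = as.list(config$initial$occupied),
      queue = as.list(config$initial$queue),
      shelter_mix = as.list(config$initial$shelter_mix),
      residual_time_rule = config$initial$residual_time_rule
    ),
    horizon = format(config$horizon),
    sample_interval_days = config$sample_interval_days,
    replications = config$replications,
    master_seed = config$master_seed,
    unit_costs = if (is.null(config$unit_costs)) NULL else as.list(config$unit_costs),
    options = config$options
  )
}

scenario_from_list <- function(l, where = "config") {
  need <- function(x, field) {
    if (is.null(x))
      stop(sprintf("%s: missing required key '%s'", where, field),
           call. = FALSE)
    x
  }
  pathways <- lapply(need(l$pathways, "pathways"), function(p) {
    pathway_spec(
      name = need(p$name, "pathways/name"),
      proportion = need(p$proportion, "pathways/proportion"),
      shelter_policy = need(p$shelter_policy, "pathways/shelter_policy"),
      shelter_stay = dist_from_list(p$shelter_stay),
      priority = if (is.null(p$priority)) 1L else p$priority,
      housing_time = dist_from_list(p$housing_time)
    )
  })
  a <- need(l$arrivals, "arrivals")
  yf <- unlist(a$year_factors)
  arrivals <- arrival_spec(
    base_rate = need(a$base_rate, "arrivals/base_rate"),
    start_date = need(a$start_date, "arrivals/start_date"),
    year_factors = if (length(yf)) yf else numeric(),
    compounding = if (is.null(a$compounding)) TRUE else a$compounding,
    fixed = if (is.null(a$fixed)) NULL else
      list(times = as.double(unlist(a$fixed$times)),
           pathways = as.integer(unlist(a$fixed$pathways)))
  )
  r <- need(l$returns, "returns")
  returns <- return_spec(
    probability = need(r$probability, "returns/probability"),
    delay = dist_from_list(need(r$delay, "returns/delay")),
    reassign_pathway = if (is.null(r$reassign_pathway)) TRUE else r$reassign_pathway
  )
  po <- need(l$policy, "policy")
  schedules <- lapply(need(po$schedules, "policy/schedules"), function(s) {
    capacity_schedule(need(s$resource, "schedules/resource"),
                      unlist(need(s$dates, "schedules/dates")),
                      unlist(need(s$units, "schedules/units")),
                      if (is.null(s$interpolation)) "linear" else s$interpolation)
  })
  policy <- investment_policy(need(po$name, "policy/name"), schedules,
                              provenance = po$provenance)
  ini <- need(l$initial, "initial")
  initial <- initial_state(
    capacity = unlist(need(ini$capacity, "initial/capacity")),
    occupied = unlist(need(ini$occupied, "initial/occupied")),
    queue = unlist(need(ini$queue, "initial/queue")),
    shelter_mix = unlist(need(ini$shelter_mix, "initial/shelter_mix")),
    residual_time_rule = if (is.null(ini$residual_time_rule))
                           "stationary_residual"
                         else ini$residual_time_rule
  )
  scenario_config(
    model = need(l$model, "model"),
    pathways = pathways, arrivals = arrivals, returns = returns,
    policy = policy, initial = initial,
    horizon = unlist(need(l$horizon, "horizon")),
    sample_interval_days = need(l$sample_interval_days, "sample_interval_days"),
    replications = need(l$replications, "replications"),
    master_seed = need(l$master_seed, "master_seed"),
    unit_costs = if (is.null(l$unit_costs)) NULL else unlist(l$unit_costs),
    options = if (is.null(l$options)) list() else l$options
  )
}

#' Read a scenario configuration file
#'
#' Scenario files are YAML (`.yaml`/`.yml`) or JSON (`.json`); the schema is
#' the one emitted by [write_scenario()]. All dates are ISO-8601 and all
#' durations are in days. Every structural invariant is checked on load.
#'
#' @param path file path.
#' @return a validated [scenario_config].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  l <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop(sprintf("unsupported scenario format '.%s' (use .yaml or .json)", ext),
         call. = FALSE)
  )
  scenario_from_list(l, where = path)
}

#' Write a scenario configuration file
#'
#' @param config a [scenario_config].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly. `load_scenario(write_scenario(x, p))`
#'   reproduces `x` field-by-field.
#' @export
write_scenario <- function(config, path) {
  validate_scenario(config)
  l <- scenario_to_list(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(l, path, precision = 15),
    json = jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
    stop(sprintf("unsupported scenario format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}
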