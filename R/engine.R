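# R-side driver for the compiled discrete-event core: flattens a validated
# scenario_config into the engine's vector encoding, realizes capacity
# schedules as unit-by-unit change events, and wraps results as
# replication_trace objects.

day_of <- function(date, day0) as.numeric(as.Date(date) - day0)

# Realize a capacity schedule as discrete (time, target) change events over
# (0, H].  Linear interpolation emits one event per integer crossing of the
# continuous interpolant; step interpolation jumps at each anchor date.
# Anchors at or before t = 0 are superseded by the initial state.
cap_events <- function(sched, day0, H, init_units) {
  days <- day_of(sched$dates, day0)
  keep <- days > 0
  pts_t <- c(0, days[keep])
  pts_c <- c(init_units, sched$units[keep])
  ev_t <- numeric(0); ev_x <- numeric(0)
  if (length(pts_t) > 1) {
    for (i in seq_len(length(pts_t) - 1)) {
      t1 <- pts_t[i]; c1 <- pts_c[i]; t2 <- pts_t[i + 1]; c2 <- pts_c[i + 1]
      if (c1 == c2) next
      if (sched$interpolation == "linear") {
        ks <- if (c2 > c1) seq(c1 + 1, c2) else seq(c1 - 1, c2)
        tt <- t1 + (t2 - t1) * abs(ks - c1) / abs(c2 - c1)
        ev_t <- c(ev_t, tt); ev_x <- c(ev_x, ks)
      } else {
        ev_t <- c(ev_t, t2); ev_x <- c(ev_x, c2)
      }
    }
  }
  keep2 <- ev_t <= H
  list(time = ev_t[keep2], target = ev_x[keep2])
}

# Piecewise-constant arrival-rate segments over [0, H): one segment per
# calendar year, rate 0 before the process start date.
arrival_segments <- function(spec, day0, H) {
  if (!is.null(spec$fixed)) return(NULL)
  end_date <- day0 + H
  years <- as.integer(format(day0, "%Y")):as.integer(format(end_date, "%Y"))
  bounds <- day_of(as.Date(paste0(years, "-01-01")), day0)
  start_day <- day_of(spec$start_date, day0)
  cuts <- sort(unique(c(0, bounds[bounds > 0 & bounds < H],
                        if (start_day > 0) start_day)))
  rates <- vapply(cuts, function(d) {
    if (d < start_day) 0 else arrival_rate_on(spec, day0 + d)
  }, numeric(1))
  list(start = cuts, rate = rates)
}

flatten_config <- function(config) {
  validate_scenario(config)
  day0 <- config$horizon[1]
  H <- day_of(config$horizon[2], day0)
  pw <- config$pathways
  n_pw <- length(pw)
  nms <- vapply(pw, `[[`, character(1), "name")
  policy_code <- c(none = 0L, until_housing = 1L, fixed_stay = 2L)
  pw_policy <- policy_code[vapply(pw, `[[`, character(1), "shelter_policy")]
  prio <- vapply(pw, `[[`, integer(1), "priority")
  pw_rank <- match(prio, sort(unique(prio))) - 1L

  stay <- lapply(pw, function(p) dist_encode(p$shelter_stay))
  house <- lapply(pw, function(p) dist_encode(p$housing_time))

  uses <- vapply(pw, `[[`, logical(1), "uses_housing")
  res_names <- nms[uses]
  pw_res <- ifelse(uses, match(nms, res_names) - 1L, -1L)
  res_pw <- match(res_names, nms) - 1L

  init <- config$initial
  get0 <- function(v, nm) if (nm %in% names(v)) as.integer(v[[nm]]) else 0L

  res_caps <- lapply(res_names, function(nm) {
    cap_events(config$policy$schedules[[nm]], day0, H, get0(init$capacity, nm))
  })
  shelter_cap <- cap_events(config$policy$schedules[["shelter"]], day0, H,
                            get0(init$capacity, "shelter"))

  seg <- arrival_segments(config$arrivals, day0, H)

  year0 <- as.integer(format(day0, "%Y"))
  year1 <- as.integer(format(config$horizon[2], "%Y"))
  year_ends <- day_of(as.Date(paste0(year0:year1, "-12-31")), day0)
  sample_times <- sort(unique(c(
    seq(0, H, by = config$sample_interval_days),
    year_ends[year_ends >= 0 & year_ends <= H], H)))

  cfg <- list(
    horizon = H,
    sample_times = sample_times,
    pw_prop = vapply(pw, `[[`, numeric(1), "proportion"),
    pw_policy = as.integer(pw_policy),
    pw_rank = as.integer(pw_rank),
    pw_res = as.integer(pw_res),
    pw_stay_kind = vapply(stay, function(e) as.integer(e$kind), integer(1)),
    pw_stay_p1 = vapply(stay, `[[`, numeric(1), "p1"),
    pw_stay_p2 = vapply(stay, `[[`, numeric(1), "p2"),
    pw_stay_p3 = vapply(stay, `[[`, numeric(1), "p3"),
    pw_house_kind = vapply(house, function(e) as.integer(e$kind), integer(1)),
    pw_house_p1 = vapply(house, `[[`, numeric(1), "p1"),
    pw_house_p2 = vapply(house, `[[`, numeric(1), "p2"),
    pw_house_p3 = vapply(house, `[[`, numeric(1), "p3"),
    res_pw = as.integer(res_pw),
    n_rank = as.integer(max(pw_rank) + 1L),
    ret_prob = config$returns$probability,
    ret_kind = dist_encode(config$returns$delay)$kind,
    ret_p1 = dist_encode(config$returns$delay)$p1,
    ret_p2 = dist_encode(config$returns$delay)$p2,
    ret_p3 = dist_encode(config$returns$delay)$p3,
    ret_reassign = config$returns$reassign_pathway,
    admission_rule = switch(config$options$admission_rule,
                            fifo_overall = 0L, shelter_first = 1L,
                            shelter_transit = 2L,
                            stop("unknown admission_rule", call. = FALSE)),
    master_seed = as.double(config$master_seed),
    residual_rule = if (identical(init$residual_time_rule,
                                  "stationary_residual")) 1L else 0L,
    shelter_init_cap = get0(init$capacity, "shelter"),
    res_init_cap = vapply(res_names, function(nm) get0(init$capacity, nm),
                          integer(1)),
    init_housing_occ = vapply(res_names, function(nm) get0(init$occupied, nm),
                              integer(1)),
    init_shelter_occ = vapply(nms, function(nm) get0(init$shelter_mix, nm),
                              integer(1)),
    init_queue = vapply(nms, function(nm) get0(init$queue, nm), integer(1)),
    shelter_cap_time = shelter_cap$time,
    shelter_cap_target = shelter_cap$target,
    res_cap_time = lapply(res_caps, `[[`, "time"),
    res_cap_target = lapply(res_caps, `[[`, "target")
  )
  if (!is.null(config$arrivals$fixed)) {
    cfg$fixed_arr_times <- as.double(config$arrivals$fixed$times)
    cfg$fixed_arr_pathway <- as.integer(config$arrivals$fixed$pathways)
  } else {
    cfg$arr_seg_start <- seg$start
    cfg$arr_seg_rate <- seg$rate
  }
  attr(cfg, "day0") <- day0
  attr(cfg, "pathway_names") <- nms
  attr(cfg, "resource_names") <- res_names
  cfg
}

.log_kind_names <- c("capacity_change", "housing_stay_end", "shelter_stay_end",
                     "arrival", "return_arrival", "housing_admit",
                     "shelter_admit")

#' Run one seeded replication of a scenario
#'
#' Executes the full discrete-event loop over the scenario horizon and
#' returns a complete trace. Identical `(config, rep_index)` always gives an
#' identical trace: all random streams derive deterministically from
#' `(master_seed, rep_index)`, and service demands are keyed per person so
#' that compared policies share common random numbers. Occupancy-bound
#' invariants are checked at every event and breach them loudly, never
#' silently.
#'
#' @param config a validated [scenario_config].
#' @param rep_index replication index, a positive integer.
#' @param record_events also return the full event log (one record per
#'   event: time, kind, person, resource, occupancy after) for blocking and
#'   conservation audits.
#' @param keep_persons keep the per-person record table (drop it to save
#'   memory in large replication batches).
#' @return an object of class `replication_trace`: sampled time series
#'   (`times`, `dates`, `shelter_occupied`, `housing_occupied`, `queued`,
#'   `sheltered`, cumulative counters), exact time-integrals of the queue
#'   and of unmet need in person-days, the per-person `persons` table, and
#'   optionally `events`.
#' @export
run_replication <- function(config, rep_index = 1L, record_events = FALSE,
                            keep_persons = TRUE) {
  flat <- flatten_config(config)
  raw <- cpp_run_replication(flat, as.integer(rep_index), record_events)
  day0 <- attr(flat, "day0")
  nms <- attr(flat, "pathway_names")
  res_names <- attr(flat, "resource_names")
  colnames(raw$housing_occupied) <- res_names
  colnames(raw$queued) <- nms
  colnames(raw$sheltered) <- nms
  persons <- NULL
  if (keep_persons) {
    persons <- as.data.frame(raw$persons)
    persons$id <- seq_len(nrow(persons))
    persons$pathway <- nms[persons$pathway]
  }
  events <- NULL
  if (record_events) {
    events <- as.data.frame(raw$events)
    events$kind <- .log_kind_names[events$kind + 1L]
    events$person <- ifelse(events$person < 0, NA_integer_,
                            events$person + 1L)
    events$resource <- ifelse(events$resource == -2L, NA_character_,
                              ifelse(events$resource == -1L, "shelter",
                                     res_names[pmax(events$resource, 0L) + 1L]))
  }
  fixed_stay <- nms[vapply(config$pathways, `[[`, character(1),
                           "shelter_policy") == "fixed_stay"]
  structure(list(
    times = raw$times,
    dates = day0 + raw$times,
    shelter_occupied = raw$shelter_occupied,
    housing_occupied = raw$housing_occupied,
    queued = raw$queued,
    sheltered = raw$sheltered,
    cum_arrivals = raw$cum_arrivals,
    cum_returns = raw$cum_returns,
    cum_exits = raw$cum_exits,
    int_queued_persondays = raw$int_queued_persondays,
    int_unmet_persondays = raw$int_unmet_persondays,
    persons = persons,
    events = events,
    pathway_names = nms,
    resource_names = res_names,
    fixed_stay_pathways = fixed_stay,
    start_date = day0,
    rep_index = as.integer(rep_index)
  ), class = "replication_trace")
}

#' @export
print.replication_trace <- function(x, ...) {
  cat(sprintf("<replication_trace> rep %d, %d sample times, %d pathway(s)\n",
              x$rep_index, length(x$times), length(x$pathway_names)))
  n <- length(x$times)
  cat(sprintf("  final: %d unsheltered, %d sheltered, %d housed, %d cum exits\n",
              sum(x$queued[n, ]), sum(x$sheltered[n, ]),
              sum(x$housing_occupied[n, ]), as.integer(x$cum_exits[n])))
  invisible(x)
}

#' Run many replications of a scenario
#'
#' @param config a [scenario_config].
#' @param reps number of replications (default `config$replications`).
#' @param keep_persons,record_events see [run_replication()].
#' @return an object of class `scenario_result`: `list(config, traces)`.
#' @export
run_scenario <- function(config, reps = NULL, keep_persons = TRUE,
                         record_events = FALSE) {
  reps <- reps %||% config$replications
  traces <- lapply(seq_len(reps), function(i) {
    run_replication(config, i, record_events = record_events,
                    keep_persons = keep_persons)
  })
  structure(list(config = config, traces = traces), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> policy '%s', %d replication(s)\n",
              x$config$policy$name, length(x$traces)))
  invisible(x)
}

#' Generate the arrival stream of a scenario replication
#'
#' Returns exactly the external (non-return) arrivals that
#' [run_replication()] would feed into the event loop for the same
#' `(config, rep_index)`: a piecewise-homogeneous Poisson process whose rate
#' changes at calendar-year boundaries, with pathways assigned by the
#' arrival mix.
#'
#' @param config a [scenario_config].
#' @param rep_index replication index.
#' @return data.frame with columns `time` (days from horizon start),
#'   `date`, and `pathway`.
#' @export
generate_arrivals <- function(config, rep_index = 1L) {
  flat <- flatten_config(config)
  day0 <- attr(flat, "day0")
  nms <- attr(flat, "pathway_names")
  if (!is.null(config$arrivals$fixed)) {
    tt <- config$arrivals$fixed$times
    pwi <- config$arrivals$fixed$pathways
  } else {
    out <- cpp_generate_arrivals(flat$arr_seg_start, flat$arr_seg_rate,
                                 flat$horizon, cumsum(flat$pw_prop),
                                 flat$master_seed, as.integer(rep_index))
    tt <- out$time
    pwi <- out$pathway
  }
  data.frame(time = tt, date = day0 + tt, pathway = nms[pwi])
}
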