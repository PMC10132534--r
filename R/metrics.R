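# Turning traces into the model's outputs: unmet-need snapshots, yearly
# summary tables, cross-replication statistics, shelter-stay distributions,
# policy costs, and CSV/JSON export.

snapshot_index <- function(trace, at) {
  d <- if (inherits(at, "Date") || is.character(at)) {
    as.numeric(as.Date(at) - trace$start_date)
  } else {
    as.numeric(at)
  }
  idx <- max(which(trace$times <= d + 1e-9))
  if (!is.finite(idx) || idx < 1)
    stop("snapshot time precedes the first sample", call. = FALSE)
  idx
}

#' Unmet need at a snapshot
#'
#' Unmet need for a pathway is the number of its people waiting in the queue
#' plus the number in emergency shelter awaiting housing. People in shelter
#' on a fixed-stay pathway (self-resolvers) are counted by default --- they
#' have not yet resolved their homelessness --- and can be excluded with
#' `include_fixed_stay = FALSE`.
#'
#' @param trace a `replication_trace`.
#' @param at snapshot date (or days from horizon start); the last sample at
#'   or before this time is used.
#' @param pathway optional pathway name; default all pathways.
#' @param include_fixed_stay count sheltered fixed-stay occupants.
#' @return named numeric vector of persons per pathway (or a single value
#'   if `pathway` given).
#' @export
unmet_need <- function(trace, at, pathway = NULL, include_fixed_stay = TRUE) {
  i <- snapshot_index(trace, at)
  shel <- trace$sheltered[i, ]
  if (!include_fixed_stay && length(trace$fixed_stay_pathways))
    shel[trace$fixed_stay_pathways] <- 0
  un <- trace$queued[i, ] + shel
  if (!is.null(pathway)) {
    if (!pathway %in% names(un))
      stop(sprintf("unknown pathway '%s'", pathway), call. = FALSE)
    return(un[[pathway]])
  }
  un
}

#' Yearly unmet-need summary table
#'
#' Year-end (Dec 31) snapshots of per-pathway unmet need, averaged over
#' replications, with a totals column --- the standard policy-comparison
#' summary.
#'
#' @param result a `scenario_result` (or list of `replication_trace`).
#' @param include_fixed_stay see [unmet_need()].
#' @return data.frame with columns `policy`, `year`, one column per
#'   pathway, and `total`.
#' @export
yearly_summary <- function(result, include_fixed_stay = TRUE) {
  traces <- if (inherits(result, "scenario_result")) result$traces else result
  if (!length(traces)) stop("need at least one trace", call. = FALSE)
  policy <- if (inherits(result, "scenario_result"))
    result$config$policy$name else "scenario"
  tr1 <- traces[[1]]
  y0 <- as.integer(format(tr1$start_date, "%Y"))
  y1 <- as.integer(format(tr1$start_date + max(tr1$times), "%Y"))
  years <- y0:y1
  years <- years[vapply(years, function(y) {
    any(abs(tr1$times - as.numeric(as.Date(paste0(y, "-12-31")) -
                                     tr1$start_date)) < 1e-9)
  }, logical(1))]
  if (!length(years)) {
    cols <- c(list(policy = character(), year = integer()),
              stats::setNames(rep(list(numeric()),
                                  length(tr1$pathway_names)),
                              tr1$pathway_names),
              list(total = numeric()))
    return(as.data.frame(cols, check.names = FALSE))
  }
  rows <- lapply(years, function(y) {
    at <- paste0(y, "-12-31")
    per <- rowMeans(vapply(traces, function(tr) {
      unmet_need(tr, at, include_fixed_stay = include_fixed_stay)
    }, numeric(length(tr1$pathway_names))))
    c(list(policy = policy, year = y), as.list(per),
      list(total = sum(per)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Cross-replication order statistics of a sampled series
#'
#' @param result a `scenario_result` or list of traces.
#' @param series one of `"unsheltered"` (total queued), `"sheltered"`,
#'   `"housing_occupied"`, `"shelter_occupied"`, `"unmet"` (queued +
#'   sheltered).
#' @return data.frame per sample time with `min`, `q1`, `median`, `q3`,
#'   `max`, `mean` across replications (quartiles use [stats::quantile()]
#'   type 7).
#' @export
replication_stats <- function(result,
                              series = c("unsheltered", "sheltered",
                                         "housing_occupied",
                                         "shelter_occupied", "unmet")) {
  series <- match.arg(series)
  traces <- if (inherits(result, "scenario_result")) result$traces else result
  pull <- function(tr) switch(series,
    unsheltered = rowSums(tr$queued),
    sheltered = rowSums(tr$sheltered),
    housing_occupied = rowSums(tr$housing_occupied),
    shelter_occupied = as.numeric(tr$shelter_occupied),
    unmet = rowSums(tr$queued) + rowSums(tr$sheltered)
  )
  m <- vapply(traces, pull, numeric(length(traces[[1]]$times)))
  qs <- t(apply(m, 1, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1)))
  data.frame(time = traces[[1]]$times, date = traces[[1]]$dates,
             min = qs[, 1], q1 = qs[, 2], median = qs[, 3], q3 = qs[, 4],
             max = qs[, 5], mean = rowMeans(m))
}

#' Completed shelter stays by exit year
#'
#' @param result a `scenario_result` or list of traces.
#' @return data.frame with one row per completed shelter stay: `year` (of
#'   shelter exit), `pathway`, `days`.
#' @export
days_in_shelter <- function(result) {
  traces <- if (inherits(result, "scenario_result")) result$traces else result
  out <- lapply(traces, function(tr) {
    if (is.null(tr$persons))
      stop("trace has no persons table (run with keep_persons = TRUE)",
           call. = FALSE)
    p <- tr$persons
    done <- !is.na(p$shelter_entry) & !is.na(p$shelter_exit)
    if (!any(done)) return(NULL)
    data.frame(
      year = as.integer(format(tr$start_date + p$shelter_exit[done], "%Y")),
      pathway = p$pathway[done],
      days = p$shelter_exit[done] - p$shelter_entry[done]
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(year = integer(), pathway = character(), days = numeric())
  else out
}

#' Operational cost of an investment policy
#'
#' `sum` over resources and years of (mean units provided that year) times
#' (user-supplied dollars per unit-year). Mean yearly units integrate the
#' schedule's interpolant over each calendar year. No default cost table is
#' shipped; per-unit costs are user input.
#'
#' @param policy an [investment_policy].
#' @param unit_costs named numeric vector, dollars per unit-year, one entry
#'   per resource in the policy.
#' @param horizon length-2 date vector over which to integrate.
#' @return total dollars.
#' @export
policy_cost <- function(policy, unit_costs, horizon) {
  horizon <- as.Date(horizon)
  missing_c <- setdiff(names(policy$schedules), names(unit_costs))
  if (length(missing_c))
    stop(sprintf("missing unit cost for resource(s): %s",
                 paste(missing_c, collapse = ", ")), call. = FALSE)
  years <- as.integer(format(horizon[1], "%Y")):as.integer(format(horizon[2], "%Y"))
  total <- 0
  for (s in policy$schedules) {
    f <- stats::approxfun(as.numeric(s$dates), s$units, method =
                            if (s$interpolation == "linear") "linear" else "constant",
                          rule = 2)
    for (y in years) {
      a <- max(as.numeric(as.Date(paste0(y, "-01-01"))), as.numeric(horizon[1]))
      b <- min(as.numeric(as.Date(paste0(y + 1, "-01-01"))), as.numeric(horizon[2]))
      if (b <= a) next
      mean_units <- stats::integrate(function(x) f(x), a, b,
                                     subdivisions = 400L)$value / (b - a)
      total <- total + mean_units * (b - a) / 365.25 * unit_costs[[s$resource_name]]
    }
  }
  total
}

#' Export a summary table or trace series
#'
#' @param x a data.frame (e.g. from [yearly_summary()] or
#'   [replication_stats()]).
#' @param path output path; format from extension (`.csv` or `.json`).
#' @return `path`, invisibly. [read_exported()] round-trips the table.
#' @export
export_table <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::write.csv(x, path, row.names = FALSE),
    json = jsonlite::write_json(x, path, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA, pretty = TRUE),
    stop(sprintf("unsupported export format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' @rdname export_table
#' @export
read_exported <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::read.csv(path, check.names = FALSE),
    json = jsonlite::fromJSON(path),
    stop(sprintf("unsupported export format '.%s'", ext), call. = FALSE)
  )
}
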