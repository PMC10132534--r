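#' Duration distribution specifications
#'
#' A `dist_spec` describes the law of a service or delay duration, always in
#' days. Four kinds are supported: `triangular(min, mode, max)`,
#' `uniform(min, max)`, `fixed(value)` and `exponential(mean)`. Triangular
#' and uniform laws are the ones used for housing occupancy times; the fixed
#' kind encodes deterministic shelter stays; the exponential kind exists so
#' that the engine can be placed in M/M/c configurations with known
#' closed-form behaviour (see [erlang_c()]).
#'
#' @param min_days,mode_days,max_days,value_days,mean_days distribution
#'   parameters, in days, all non-negative.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_triangular(0, 6 * 365.25, 8 * 365.25)  # aggregate housing time
#' dist_fixed(152)                             # a five-month shelter stay
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_triangular <- function(min_days, mode_days, max_days) {
  new_dist("triangular", c(min = min_days, mode = mode_days, max = max_days))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min_days, max_days) {
  new_dist("uniform", c(min = min_days, max = max_days))
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value_days) {
  new_dist("fixed", c(value = value_days))
}

#' @rdname dist_spec
#' @export
dist_exponential <- function(mean_days) {
  new_dist("exponential", c(mean = mean_days))
}

new_dist <- function(kind, params) {
  x <- structure(list(kind = kind, params = as.list(params)),
                 class = "dist_spec")
  validate_dist(x)
  x
}

validate_dist <- function(x) {
  if (!inherits(x, "dist_spec")) stop("not a dist_spec", call. = FALSE)
  p <- x$params
  bad <- function(msg) {
    stop(sprintf("invalid %s distribution: %s", x$kind, msg), call. = FALSE)
  }
  if (any(unlist(p) < 0)) bad("all parameters must be >= 0")
  switch(x$kind,
    triangular = {
      if (!(p$min <= p$mode && p$mode <= p$max)) bad("need min <= mode <= max")
      if (!(p$min < p$max)) bad("need min < max")
    },
    uniform = if (!(p$min < p$max)) bad("need min < max"),
    fixed = invisible(NULL),
    exponential = if (!(p$mean > 0)) bad("need mean > 0"),
    bad("unknown kind")
  )
  invisible(x)
}

# engine encoding: kind code + three parameter slots
.dist_kind_code <- c(triangular = 0L, uniform = 1L, fixed = 2L, exponential = 3L)

dist_encode <- function(x) {
  if (is.null(x)) return(list(kind = -1L, p1 = 0, p2 = 0, p3 = 0))
  p <- x$params
  switch(x$kind,
    triangular  = list(kind = 0L, p1 = p$min, p2 = p$mode, p3 = p$max),
    uniform     = list(kind = 1L, p1 = p$min, p2 = p$max, p3 = 0),
    fixed       = list(kind = 2L, p1 = p$value, p2 = 0, p3 = 0),
    exponential = list(kind = 3L, p1 = p$mean, p2 = 0, p3 = 0)
  )
}

#' Mean of a duration distribution
#'
#' Closed-form mean, in days.
#'
#' @param x a [dist_spec].
#' @return mean duration in days.
#' @export
dist_mean <- function(x) {
  validate_dist(x)
  p <- x$params
  switch(x$kind,
    triangular = (p$min + p$mode + p$max) / 3,
    uniform = (p$min + p$max) / 2,
    fixed = p$value,
    exponential = p$mean
  )
}

#' Draw durations from a distribution specification
#'
#' Sampling uses the same inverse-CDF code as the simulation engine (the
#' triangular law is inverted analytically), so empirical checks against
#' [triangular_cdf()] exercise the engine's sampler itself.
#'
#' @param dist a [dist_spec].
#' @param n number of draws.
#' @param seed integer seed for the dedicated sampling stream.
#' @return numeric vector of `n` durations in days.
#' @export
sample_duration <- function(dist, n, seed = 1L) {
  validate_dist(dist)
  e <- dist_encode(dist)
  cpp_sample_duration(e$kind, e$p1, e$p2, e$p3, as.integer(n), as.double(seed))
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- unlist(x$params)
  cat(sprintf("<dist_spec> %s(%s) days\n", x$kind,
              paste(sprintf("%s=%g", names(p), p), collapse = ", ")))
  invisible(x)
}

dist_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  c(list(kind = x$kind), x$params)
}

dist_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  switch(l$kind,
    triangular = dist_triangular(l$min, l$mode, l$max),
    uniform = dist_uniform(l$min, l$max),
    fixed = dist_fixed(l$value),
    exponential = dist_exponential(l$mean),
    stop(sprintf("unknown distribution kind '%s'", l$kind), call. = FALSE)
  )
}
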