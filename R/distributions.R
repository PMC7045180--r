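#' Activity-duration distributions
#'
#' All delays in the pathway model are non-negative and right-skewed, and the
#' only published information about them is a median and an interquartile
#' range.  A two-parameter lognormal anchored at the median is therefore used
#' as the working family: the location parameter is `log(median)` and the
#' spread is matched to the quartiles symmetrically on the log scale.
#' Degenerate delays (a stage that takes a fixed time, or has been eliminated
#' altogether) are represented explicitly as a point mass rather than as a
#' limit of lognormals, and an optional hard cap truncates samples from above
#' (mass accumulates at the cap, it is not redistributed).
#'
#' @param family `"lognormal"` or `"point_mass"`.
#' @param meanlog Location on the log-minute scale (lognormal only).
#' @param sdlog Spread, dimensionless, `>= 0` (lognormal only).
#' @param value Minutes at which the point mass sits (point mass only).
#' @param cap Optional upper bound in minutes; samples are `pmin`-ed to it.
#'
#' @return An object of class `duration_dist`.
#' @seealso [fit_quantiles()], [dd_sample()], [dd_scale_median()],
#'   [dd_truncate()]
#' @export
duration_dist <- function(family = c("lognormal", "point_mass"),
                          meanlog = NULL, sdlog = NULL, value = NULL,
                          cap = NULL) {
  family <- match.arg(family)
  if (family == "lognormal") {
    stopifnot(is.numeric(meanlog), length(meanlog) == 1L, is.finite(meanlog),
              is.numeric(sdlog), length(sdlog) == 1L, sdlog >= 0)
    if (sdlog == 0) {
      # zero spread is a point mass by definition
      return(duration_dist("point_mass", value = exp(meanlog), cap = cap))
    }
    value <- NULL
  } else {
    stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
    meanlog <- NULL
    sdlog <- 0
  }
  if (!is.null(cap)) {
    stopifnot(is.numeric(cap), length(cap) == 1L, cap > 0)
    if (is.infinite(cap)) cap <- NULL
  }
  structure(list(family = family, meanlog = meanlog, sdlog = sdlog,
                 value = value, cap = cap),
            class = "duration_dist")
}

#' @export
print.duration_dist <- function(x, ...) {
  if (x$family == "point_mass") {
    cat(sprintf("<duration_dist> point mass at %.4g min", x$value))
  } else {
    cat(sprintf("<duration_dist> lognormal(meanlog = %.4f, sdlog = %.4f), median %.4g min",
                x$meanlog, x$sdlog, exp(x$meanlog)))
  }
  if (!is.null(x$cap)) cat(sprintf(", capped at %.4g min", x$cap))
  cat("\n")
  invisible(x)
}

is_point_mass <- function(d) d$family == "point_mass"

#' Fit a duration distribution from a median and interquartile range
#'
#' Closed-form two-quantile match: the lognormal location is set so the
#' distribution median equals the summary median exactly, and the spread is
#' `(log(q3) - log(q1)) / (2 * qnorm(0.75))`, i.e. the quartiles are matched
#' symmetrically on the log scale.  When the printed IQR is asymmetric around
#' the median on the log scale (as heavily skewed delays are), the fitted
#' quartiles reproduce the quartile ratio `q3/q1` exactly but not each
#' endpoint; the residuals are returned in the `fit` attribute.  A degenerate
#' summary (`q1 == median == q3`) yields a point mass.
#'
#' @param median,q1,q3 Summary quantiles in minutes, `0 <= q1 <= median <= q3`.
#' @return A [duration_dist()] with attribute `fit` (a list with the input
#'   summary, the implied quartiles and their relative residuals).
#' @examples
#' fit_quantiles(35, 25, 45)   # door-to-needle: lognormal(3.5553, 0.4357)
#' fit_quantiles(10, 10, 10)   # point mass at 10
#' @export
fit_quantiles <- function(median, q1, q3) {
  stopifnot(is.numeric(median), is.numeric(q1), is.numeric(q3),
            length(median) == 1L, length(q1) == 1L, length(q3) == 1L)
  if (!is.finite(median) || !is.finite(q1) || !is.finite(q3) ||
      q1 < 0 || q1 > median || median > q3) {
    stop("invalid quantile summary: need 0 <= q1 <= median <= q3, all finite")
  }
  if (q1 == q3) {
    return(duration_dist("point_mass", value = median))
  }
  if (median <= 0 || q1 <= 0) {
    stop("non-degenerate fit needs median > 0 and q1 > 0")
  }
  sdlog <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  d <- duration_dist("lognormal", meanlog = log(median), sdlog = sdlog)
  fitted_q <- dd_quartiles(d)
  attr(d, "fit") <- list(
    summary = c(median = median, q1 = q1, q3 = q3),
    fitted = fitted_q,
    residual = c(q1 = fitted_q[["q1"]] / q1 - 1,
                 q3 = fitted_q[["q3"]] / q3 - 1))
  d
}

#' Median and quartiles of a duration distribution
#'
#' Analytic values, honouring any truncation cap.
#' @param d A [duration_dist()].
#' @return `dd_median()`: a scalar; `dd_quartiles()`: named vector
#'   `c(q1, median, q3)`.
#' @export
dd_median <- function(d) {
  m <- if (is_point_mass(d)) d$value else exp(d$meanlog)
  if (!is.null(d$cap)) m <- min(m, d$cap)
  m
}

#' @rdname dd_median
#' @export
dd_quartiles <- function(d) {
  if (is_point_mass(d)) {
    q <- rep(d$value, 3)
  } else {
    q <- stats::qlnorm(c(0.25, 0.5, 0.75), d$meanlog, d$sdlog)
  }
  if (!is.null(d$cap)) q <- pmin(q, d$cap)
  names(q) <- c("q1", "median", "q3")
  q
}

#' Rescale a distribution to a new median
#'
#' Scenario changes of the form "median delay reduced to X minutes" are
#' modelled by multiplying the whole distribution by the ratio of the target
#' to the current median: on the log scale the location shifts by
#' `log(target/current)` and the spread is unchanged, so the quartile ratio
#' `q3/q1` (relative dispersion) is preserved exactly.  A target of zero
#' collapses the stage to a point mass at zero.  Any truncation cap is scaled
#' by the same ratio.
#'
#' @param d A [duration_dist()].
#' @param target_median New median in minutes, `>= 0`.
#' @return A new [duration_dist()].
#' @export
dd_scale_median <- function(d, target_median) {
  stopifnot(is.numeric(target_median), length(target_median) == 1L)
  if (!is.finite(target_median) || target_median < 0) {
    stop("target median must be finite and >= 0")
  }
  if (target_median == 0) {
    return(duration_dist("point_mass", value = 0))
  }
  cur <- dd_median(d)
  if (cur == 0) stop("cannot rescale a point mass at zero to a positive median")
  ratio <- target_median / cur
  cap <- if (!is.null(d$cap)) d$cap * ratio else NULL
  if (is_point_mass(d)) {
    duration_dist("point_mass", value = target_median, cap = cap)
  } else {
    duration_dist("lognormal", meanlog = d$meanlog + log(ratio),
                  sdlog = d$sdlog, cap = cap)
  }
}

#' Impose a hard upper bound on a delay
#'
#' Samples are truncated as `min(x, cap)`: probability mass accumulates at the
#' cap instead of being redistributed, which keeps scenario effects monotone
#' (a tighter cap never lengthens any delay).  The mean never increases and an
#' infinite cap is the identity.
#'
#' @param d A [duration_dist()].
#' @param cap Upper bound in minutes, `> 0`.
#' @return A new [duration_dist()].
#' @export
dd_truncate <- function(d, cap) {
  stopifnot(is.numeric(cap), length(cap) == 1L)
  if (!is.finite(cap) && cap > 0) return(d)
  if (!(cap > 0)) stop("cap must be > 0")
  new_cap <- if (!is.null(d$cap)) min(d$cap, cap) else cap
  if (is_point_mass(d)) {
    duration_dist("point_mass", value = min(d$value, new_cap))
  } else {
    duration_dist("lognormal", meanlog = d$meanlog, sdlog = d$sdlog,
                  cap = new_cap)
  }
}

#' Sample durations
#'
#' Draws `n` values from the distribution using the current R random number
#' stream (seed management is the caller's responsibility, see
#' [run_replications()]).  All draws are non-negative; a cap is applied as
#' `pmin`.
#'
#' @param d A [duration_dist()].
#' @param n Number of draws, `>= 1`.
#' @return Numeric vector of minutes, length `n`.
#' @export
dd_sample <- function(d, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  x <- if (is_point_mass(d)) rep.int(d$value, n) else stats::rlnorm(n, d$meanlog, d$sdlog)
  if (!is.null(d$cap)) x <- pmin(x, d$cap)
  x
}

# --- serialisation ---------------------------------------------------------

dist_to_list <- function(d, activity = NULL) {
  # summarise the underlying (uncapped) distribution; the cap is its own field
  uncapped <- d
  uncapped$cap <- NULL
  q <- dd_quartiles(uncapped)
  out <- list(activity = activity, family = d$family,
              median = unname(q[["median"]]),
              q1 = unname(q[["q1"]]), q3 = unname(q[["q3"]]),
              cap = if (is.null(d$cap)) NA_real_ else d$cap)
  if (is.null(activity)) out$activity <- NULL
  out
}

dist_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(x$family))
  cap <- if (is.null(x$cap) || is.na(x$cap)) NULL else x$cap
  if (x$family == "point_mass") {
    d <- duration_dist("point_mass", value = x$median, cap = cap)
  } else {
    d <- fit_quantiles(x$median, x$q1, x$q3)
    if (!is.null(cap)) d <- dd_truncate(d, cap)
  }
  d
}

#' Read and write a distribution library
#'
#' A distribution library is a JSON array of records
#' `{activity, family, median, q1, q3, cap}`; the package ships one under
#' `inst/extdata/activity_distributions.json` holding the baseline cohort
#' summaries from which [baseline_config()] is built.
#'
#' @param path File path.
#' @return `read_distribution_library()`: a named list of [duration_dist()]
#'   keyed by activity.
#' @export
read_distribution_library <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(recs, dist_from_list)
  names(out) <- vapply(recs, `[[`, "", "activity")
  out
}

#' @rdname read_distribution_library
#' @param dists Named list of [duration_dist()].
#' @export
write_distribution_library <- function(dists, path) {
  stopifnot(is.list(dists), !is.null(names(dists)))
  recs <- lapply(names(dists), function(a) dist_to_list(dists[[a]], activity = a))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}
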