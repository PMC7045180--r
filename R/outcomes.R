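#' Treatment-benefit coefficients
#'
#' The benefit of IVT declines steeply with onset-to-treatment time.  The
#' model carries one attributable-benefit fraction per treatment-time band --
#' the reciprocal numbers-needed-to-treat 1/4.5, 1/9 and 1/14.1 for treatment
#' within 0-90, 91-180 and 181-270 minutes -- and a linear exchange rate of
#' 1.8 additional healthy-life days per minute of OTT reduction.  The band
#' coefficients must be strictly decreasing (earlier treatment always helps
#' more) and lie in (0, 1).
#'
#' @param band_benefit Numeric length-3 vector of per-band benefit fractions.
#' @param healthy_days_per_min Days of healthy life gained per minute of OTT
#'   reduction.
#' @return A list of class `benefit_coefficients`.
#' @export
benefit_coefficients <- function(band_benefit = c(1 / 4.5, 1 / 9, 1 / 14.1),
                                 healthy_days_per_min = 1.8) {
  stopifnot(length(band_benefit) == 3, all(band_benefit > 0),
            all(band_benefit < 1), all(diff(band_benefit) < 0),
            healthy_days_per_min > 0)
  structure(list(band_benefit = band_benefit,
                 healthy_days_per_min = healthy_days_per_min),
            class = "benefit_coefficients")
}

#' Replication-based confidence interval
#'
#' Normal-approximation interval for the mean of a per-replication outcome:
#' `mean +/- z * sd / sqrt(R)`.  The width shrinks as `1/sqrt(R)`, so interval
#' width reflects the chosen replication count, not patient-level sampling
#' alone.
#'
#' @param values Numeric vector, one value per replication (length `>= 2`);
#'   `NA`s (replications where the outcome is undefined) are dropped.
#' @param level Coverage, default 0.95.
#' @return Named vector `c(mean, lo, hi)`.
#' @export
mc_confidence_interval <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 replications")
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(values)
  half <- z * stats::sd(values) / sqrt(length(values))
  c(mean = m, lo = m - half, hi = m + half)
}

#' Attributable excellent outcome
#'
#' Proportion of treated patients whose excellent functional outcome
#' (modified Rankin Scale 0-1 at 90 days) is attributable to IVT: the
#' band-share-weighted mean of the per-band benefit fractions, as a
#' percentage.  Shares are conditional on treatment, so the result is bounded
#' by the smallest and largest band coefficient.
#'
#' @param band_shares Length-3 fractions over the OTT bands, summing to 1.
#' @param coeff A [benefit_coefficients()].
#' @param digits Rounding for reporting (default 1 decimal, as published);
#'   `NULL` for full precision.
#' @return Percent (scalar).
#' @export
attributable_mrs01 <- function(band_shares, coeff = benefit_coefficients(),
                               digits = 1) {
  stopifnot(length(band_shares) == 3, all(band_shares >= 0))
  if (abs(sum(band_shares) - 1) > 1e-3) {
    stop("band shares must sum to 1 (conditional on treatment)")
  }
  pct <- 100 * sum(band_shares * coeff$band_benefit)
  if (is.null(digits)) pct else round(pct, digits)
}

#' Extra healthy-life days from faster treatment
#'
#' Linear benefit model: `healthy_days_per_min * (ott_base - ott_scenario)`.
#' Zero when the OTT is unchanged; negative if a scenario worsens it.
#'
#' @param ott_base,ott_scenario Mean OTT among treated, minutes.
#' @param coeff A [benefit_coefficients()].
#' @return Days (scalar).
#' @export
extra_healthy_days <- function(ott_base, ott_scenario,
                               coeff = benefit_coefficients()) {
  stopifnot(ott_base >= 0, ott_scenario >= 0)
  coeff$healthy_days_per_min * (ott_base - ott_scenario)
}

#' Pearson chi-squared test for two proportions
#'
#' Compares `k1/n1` against `k2/n2` with the Pearson chi-squared statistic on
#' the 2x2 table, without continuity correction, as used to flag significant
#' scenario-versus-baseline differences in treatment rates.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @return Named vector `c(statistic, p)`.
#' @export
chi_square_2x2 <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(colSums(tab) == 0)) stop("degenerate table: empty margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  c(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Evaluate one scenario
#'
#' Applies a scenario to the base configuration, runs replicated simulations
#' and aggregates the published outcome columns: IVT rate with 95% CI, mean
#' OTT among treated with 95% CI, band shares (pooled over all treated
#' patients across replications), attributable mRS 0-1 percentage and -- when
#' a baseline OTT is supplied -- extra healthy-life days.
#'
#' @param base A [pathway_config()].
#' @param spec A [scenario_spec()].
#' @param n_patients,n_reps,seed Passed to [run_replications()].
#' @param coeff A [benefit_coefficients()].
#' @param baseline_ott Mean baseline OTT (minutes) for the healthy-days
#'   column; `NA` for the baseline row itself.
#' @return A one-row data.frame (a `scenario_result`).
#' @export
evaluate_scenario <- function(base, spec, n_patients = 280, n_reps = 1000,
                              seed = 1, coeff = benefit_coefficients(),
                              baseline_ott = NA_real_) {
  cfg <- apply_scenario(base, spec)
  reps <- run_replications(cfg, n_patients, n_reps, seed)
  rate_ci <- mc_confidence_interval(reps$ivt_rate)
  ott_ci <- if (all(is.na(reps$mean_ott_treated))) {
    c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
  } else {
    mc_confidence_interval(reps$mean_ott_treated)
  }
  # pool treated patients over replications for stable band shares
  tot_treated <- sum(reps$n_treated)
  shares <- if (tot_treated > 0) {
    colSums(reps[, c("band_0_90", "band_91_180", "band_181_270")] *
              reps$n_treated, na.rm = TRUE) / tot_treated
  } else {
    rep(NA_real_, 3)
  }
  mrs <- if (tot_treated > 0) attributable_mrs01(shares, coeff) else NA_real_
  days <- if (!is.na(baseline_ott) && !is.na(ott_ci[["mean"]])) {
    extra_healthy_days(baseline_ott, ott_ci[["mean"]], coeff)
  } else {
    NA_real_
  }
  data.frame(
    scenario = spec$id, description = spec$description,
    ivt_rate = 100 * rate_ci[["mean"]],
    ivt_lo = 100 * rate_ci[["lo"]], ivt_hi = 100 * rate_ci[["hi"]],
    ott = ott_ci[["mean"]], ott_lo = ott_ci[["lo"]], ott_hi = ott_ci[["hi"]],
    band_0_90 = 100 * shares[[1]], band_91_180 = 100 * shares[[2]],
    band_181_270 = 100 * shares[[3]],
    mrs01 = mrs, extra_days = days,
    arrival_within_270 = 100 * mean(reps$arrival_within_270),
    stringsAsFactors = FALSE
  )
}

#' Assemble the scenario results table
#'
#' Binds per-scenario results into the published table layout, recomputes the
#' healthy-days column against the baseline row, and flags scenarios whose
#' treatment rate differs significantly from baseline (Pearson chi-squared on
#' the cohort-scale 2x2 table, p < 0.05).
#'
#' @param results List of one-row data.frames from [evaluate_scenario()]; the
#'   baseline row is the one with scenario id `"0"` (must be present).
#' @param n_patients Cohort size used for the chi-squared comparison.
#' @param coeff A [benefit_coefficients()].
#' @return A data.frame, one row per scenario, in input order.
#' @export
results_table <- function(results, n_patients = 280,
                          coeff = benefit_coefficients()) {
  tab <- do.call(rbind, results)
  if (!"0" %in% tab$scenario) stop("baseline scenario \"0\" missing")
  base <- tab[tab$scenario == "0", ]
  tab$extra_days <- ifelse(
    tab$scenario == "0", NA_real_,
    coeff$healthy_days_per_min * (base$ott - tab$ott))
  k_base <- round(base$ivt_rate / 100 * n_patients)
  tab$sig_vs_baseline <- vapply(seq_len(nrow(tab)), function(i) {
    if (tab$scenario[i] == "0") return(FALSE)
    k <- round(tab$ivt_rate[i] / 100 * n_patients)
    if (k == k_base) return(FALSE)
    chi_square_2x2(k, n_patients, k_base, n_patients)[["p"]] < 0.05
  }, logical(1))
  rownames(tab) <- NULL
  tab
}

#' Export a results table
#'
#' Writes the scenario results to CSV (values as printed) or JSON (full
#' precision; round-trips bitwise through [read_results_table()]).
#'
#' @param tab A data.frame from [results_table()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(tab, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(scenario = "character"))
  }
}
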