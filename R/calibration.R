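#' Calibrate the free pathway parameters
#'
#' Three model parameters are unobserved and are fixed against published
#' cohort statistics:
#'
#' * `p_contra`, the intrinsic ineligibility probability, is identified
#'   analytically: in the fully optimised pathway every delay is zero and
#'   diagnostics are perfect, so the treatment rate equals `1 - p_contra`;
#'   hence `p_contra = 1 - optimised_rate` (0.023 at the default targets).
#' * The GP-consult and self-transport medians are found by coordinate search
#'   (coarse log-scale grid, then golden-section refinement per coordinate)
#'   minimising the summed squared error of the simulated arrival-within-4.5 h
#'   fraction, IVT rate and treated-within-90-min share against their targets.
#' * `diagnostic_quality` is profiled analytically at every evaluation: the
#'   expected IVT rate factorises as
#'   `time_eligible * (1 - p_contra) * quality`, so the quality that matches
#'   the IVT target given the simulated time-eligible fraction is
#'   `target / ((1 - p_contra) * time_eligible)`, clamped to `(0, 1]`.
#'
#' Every objective evaluation simulates one pooled cohort of
#' `n_reps_eval * n_patients` patients from the same evaluation seed (common
#' random numbers), which makes the search deterministic given `seed` and the
#' objective smooth in the medians.
#'
#' @param base A [pathway_config()] whose GP-consult and self-transport
#'   distributions carry the prior shapes (their log-scale spreads are kept;
#'   only the medians are searched).
#' @param targets A [calibration_targets()] list.
#' @param n_patients,n_reps_eval Evaluation sample: `n_reps_eval` cohorts of
#'   `n_patients` pooled per objective call (default 500 x 280).
#' @param seed Integer seed.
#' @param budget Maximum number of objective evaluations (`>= 100`).
#' @param median_range Search interval (minutes) for both medians.
#' @return A list of class `calibration_result`: `config` (the calibrated
#'   [pathway_config()]), `params` (named list of the fixed free parameters),
#'   `achieved` vs `targets` report, `loss`, `n_eval`, and `converged`
#'   (FALSE when the budget was exhausted before refinement finished).
#' @export
calibrate_pathway <- function(base, targets = calibration_targets(),
                              n_patients = 280, n_reps_eval = 500,
                              seed = 1, budget = 300,
                              median_range = c(5, 480)) {
  stopifnot(inherits(base, "pathway_config"), budget >= 100)
  p_contra <- 1 - targets$optimised_rate
  n_eval_patients <- n_reps_eval * n_patients
  set.seed(seed)
  eval_seed <- sample.int(.Machine$integer.max - 1L, 1)

  n_eval <- 0L
  best <- list(loss = Inf)
  target_vec <- c(targets$ivt_rate, targets$arrival_within_270,
                  targets$band1_share_treated)

  objective <- function(m_gp, m_st) {
    n_eval <<- n_eval + 1L
    cfg <- base
    cfg$p_contra <- p_contra
    cfg$diagnostic_quality <- 1
    cfg$dists$gp_consult <- dd_scale_median(cfg$dists$gp_consult, m_gp)
    cfg$dists$self_transport <- dd_scale_median(cfg$dists$self_transport, m_st)
    set.seed(eval_seed)
    coh <- simulate_cohort(cfg, n_eval_patients)
    elig <- mean(coh$time_eligible)
    arrival <- mean(coh$onset_to_door <= cfg$treatment_window)
    # quality thins eligibility uniformly, so the treated band-1 share equals
    # the time-eligible band-1 share and quality can be profiled analytically
    band1 <- mean((coh$onset_to_door + coh$dtn)[coh$time_eligible] <= 90)
    quality <- min(1, targets$ivt_rate / ((1 - p_contra) * max(elig, 1e-12)))
    achieved <- c(elig * (1 - p_contra) * quality, arrival, band1)
    loss <- sum((achieved - target_vec)^2)
    state <- list(loss = loss, m_gp = m_gp, m_st = m_st, quality = quality,
                  achieved = stats::setNames(as.list(achieved),
                                             c("ivt_rate", "arrival_within_270",
                                               "band1_share_treated")))
    if (loss < best$loss) best <<- state
    loss
  }

  # coarse grid, log-spaced
  grid <- exp(seq(log(median_range[1]), log(median_range[2]), length.out = 11))
  for (m_gp in grid) for (m_st in grid) {
    if (n_eval >= budget) break
    objective(m_gp, m_st)
  }

  # golden-section refinement, one coordinate at a time on the log scale
  golden <- function(f, lo, hi, n_iter = 10) {
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- f(x1); f2 <- f(x2)
    for (i in seq_len(n_iter)) {
      if (f1 < f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- f(x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- f(x2)
      }
    }
    if (f1 < f2) x1 else x2
  }
  span <- log(grid[2] / grid[1]) * 1.5
  converged <- TRUE
  for (pass in 1:2) {
    for (coord in c("m_gp", "m_st")) {
      if (n_eval + 12 > budget) { converged <- FALSE; break }
      centre <- log(best[[coord]])
      lo <- max(log(median_range[1]), centre - span)
      hi <- min(log(median_range[2]), centre + span)
      f <- if (coord == "m_gp") {
        function(x) objective(exp(x), best$m_st)
      } else {
        function(x) objective(best$m_gp, exp(x))
      }
      golden(f, lo, hi)
    }
  }

  params <- list(gp_consult_median = best$m_gp,
                 self_transport_median = best$m_st,
                 diagnostic_quality = best$quality,
                 p_contra = p_contra)
  config <- base
  config$p_contra <- p_contra
  config$diagnostic_quality <- best$quality
  config$dists$gp_consult <- dd_scale_median(config$dists$gp_consult, best$m_gp)
  config$dists$self_transport <- dd_scale_median(config$dists$self_transport,
                                                 best$m_st)
  structure(list(config = config, params = params,
                 achieved = best$achieved, targets = targets,
                 loss = best$loss, n_eval = n_eval, converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  gp_consult median     %7.1f min\n", x$params$gp_consult_median))
  cat(sprintf("  self_transport median %7.1f min\n", x$params$self_transport_median))
  cat(sprintf("  diagnostic quality    %7.3f\n", x$params$diagnostic_quality))
  cat(sprintf("  p_contra              %7.3f (analytic)\n", x$params$p_contra))
  cat(sprintf("  evaluations %d, converged %s\n", x$n_eval, x$converged))
  for (nm in names(x$achieved)) {
    cat(sprintf("  %-22s achieved %.3f, target %.3f\n", nm,
                x$achieved[[nm]], x$targets[[nm]]))
  }
  invisible(x)
}
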