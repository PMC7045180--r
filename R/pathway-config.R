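#' Pathway configuration
#'
#' The full parameter set of the simulation model: the referral mix, one
#' duration distribution per pathway activity, the two eligibility windows,
#' the intrinsic (time-independent) ineligibility probability `p_contra`, and
#' the diagnostic-quality probability (the chance that a time-eligible patient
#' is correctly worked up as an IVT candidate).
#'
#' Eligibility is a two-window rule: a patient can be treated only if they
#' reach the door within `arrival_window` minutes of onset *and* the needle
#' time (door time plus door-to-needle delay) falls within `treatment_window`
#' minutes, the licence limit for IVT.  On top of the time windows, treatment
#' requires passing two independent Bernoulli gates: no intrinsic
#' contraindication (probability `1 - p_contra`) and a positive diagnostic
#' work-up (probability `diagnostic_quality`).
#'
#' @param route_mix Named probabilities over
#'   `c("gp", "call_911", "self_referral", "in_hospital")`, summing to 1.
#' @param dists Named list of [duration_dist()] with elements `patient_delay`,
#'   `responder_response`, `gp_consult`, `on_scene`, `transport`,
#'   `self_transport`, `dtn`.
#' @param treatment_window Minutes from onset within which the needle must go
#'   in (default 270, the 4.5 h licence window).
#' @param arrival_window Minutes from onset within which the patient must
#'   reach the door to still be worked up (default 240).
#' @param p_contra Probability of intrinsic contraindication, in `[0, 1]`.
#' @param diagnostic_quality Probability a time-eligible patient is diagnosed
#'   as an IVT candidate, in `[0, 1]`.
#'
#' @return An object of class `pathway_config`.
#' @export
pathway_config <- function(route_mix, dists,
                           treatment_window = 270, arrival_window = 240,
                           p_contra = 0, diagnostic_quality = 1) {
  routes <- c("gp", "call_911", "self_referral", "in_hospital")
  stopifnot(is.numeric(route_mix), setequal(names(route_mix), routes))
  route_mix <- route_mix[routes]
  if (any(route_mix < 0) || abs(sum(route_mix) - 1) > 1e-9) {
    stop("route_mix must be non-negative and sum to 1")
  }
  needed <- c("patient_delay", "responder_response", "gp_consult", "on_scene",
              "transport", "self_transport", "dtn")
  stopifnot(is.list(dists), all(needed %in% names(dists)))
  for (nm in needed) {
    if (!inherits(dists[[nm]], "duration_dist")) {
      stop("dists$", nm, " is not a duration_dist")
    }
  }
  stopifnot(treatment_window > 0, arrival_window > 0,
            arrival_window <= treatment_window,
            p_contra >= 0, p_contra <= 1,
            diagnostic_quality >= 0, diagnostic_quality <= 1)
  structure(list(route_mix = route_mix, dists = dists[needed],
                 treatment_window = treatment_window,
                 arrival_window = arrival_window,
                 p_contra = p_contra,
                 diagnostic_quality = diagnostic_quality),
            class = "pathway_config")
}

#' @export
print.pathway_config <- function(x, ...) {
  cat("<pathway_config>\n")
  cat("  route mix: ", paste(sprintf("%s %.1f%%", names(x$route_mix),
                                     100 * x$route_mix), collapse = ", "), "\n")
  for (nm in names(x$dists)) {
    q <- dd_quartiles(x$dists[[nm]])
    cat(sprintf("  %-20s median %6.1f min (IQR %.1f-%.1f)%s\n", nm,
                q[["median"]], q[["q1"]], q[["q3"]],
                if (!is.null(x$dists[[nm]]$cap))
                  sprintf(", cap %.0f", x$dists[[nm]]$cap) else ""))
  }
  cat(sprintf("  windows: arrival <= %.0f min, needle <= %.0f min\n",
              x$arrival_window, x$treatment_window))
  cat(sprintf("  p_contra = %.3f, diagnostic quality = %.3f\n",
              x$p_contra, x$diagnostic_quality))
  invisible(x)
}

#' Baseline pathway configuration
#'
#' Builds the uncalibrated baseline model from the packaged distribution
#' library: lognormal fits to the observed activity summaries, the observed
#' referral mix, default windows (arrival 240 min, needle 270 min) and the
#' intrinsic ineligibility implied by the optimised-pathway treatment rate
#' (`p_contra = 1 - 0.977`).  The general-practitioner consult and
#' self-referral transport distributions carry prior medians and
#' `diagnostic_quality` is 1; run [calibrate_pathway()] to fix these free
#' parameters against the cohort targets.
#'
#' @param calibrated Optional named list with elements `gp_consult_median`,
#'   `self_transport_median`, `diagnostic_quality` (as returned by
#'   [calibrate_pathway()]) to apply to the baseline.
#' @return A [pathway_config()].
#' @export
baseline_config <- function(calibrated = NULL) {
  lib_path <- system.file("extdata", "activity_distributions.json",
                          package = "strokesim")
  dists <- if (nzchar(lib_path)) {
    read_distribution_library(lib_path)
  } else {
    aq <- activity_quantiles()
    stats::setNames(
      lapply(seq_len(nrow(aq)), function(i) fit_quantiles(aq$median[i], aq$q1[i], aq$q3[i])),
      aq$activity)
  }
  cfg <- pathway_config(
    route_mix = baseline_route_mix(),
    dists = dists,
    p_contra = 1 - calibration_targets()$optimised_rate,
    diagnostic_quality = 1
  )
  if (!is.null(calibrated)) {
    cfg$dists$gp_consult <- dd_scale_median(cfg$dists$gp_consult,
                                            calibrated$gp_consult_median)
    cfg$dists$self_transport <- dd_scale_median(cfg$dists$self_transport,
                                                calibrated$self_transport_median)
    cfg$diagnostic_quality <- calibrated$diagnostic_quality
  }
  cfg
}

# --- serialisation ---------------------------------------------------------

config_to_list <- function(config) {
  list(
    route_mix = as.list(config$route_mix),
    dists = lapply(names(config$dists), function(nm)
      dist_to_list(config$dists[[nm]], activity = nm)),
    treatment_window = config$treatment_window,
    arrival_window = config$arrival_window,
    p_contra = config$p_contra,
    diagnostic_quality = config$diagnostic_quality
  )
}

config_from_list <- function(x) {
  dists <- lapply(x$dists, dist_from_list)
  names(dists) <- vapply(x$dists, `[[`, "", "activity")
  pathway_config(
    route_mix = unlist(x$route_mix),
    dists = dists,
    treatment_window = x$treatment_window,
    arrival_window = x$arrival_window,
    p_contra = x$p_contra,
    diagnostic_quality = x$diagnostic_quality
  )
}

#' Read and write pathway configurations
#'
#' Configurations round-trip through YAML (human-edited scenario work) or
#' JSON; the format is chosen from the file extension.
#'
#' @param config A [pathway_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_pathway_config()` returns a [pathway_config()];
#'   `write_pathway_config()` returns `path` invisibly.
#' @export
write_pathway_config <- function(config, path) {
  x <- config_to_list(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_pathway_config
#' @export
read_pathway_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  config_from_list(x)
}
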