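ott_band_breaks <- c(0, 90, 180, 270)
ott_band_labels <- c("0-90", "91-180", "181-270")

#' Classify onset-to-treatment times into benefit bands
#'
#' Bands are closed on the right -- `[0, 90]`, `(90, 180]`, `(180, 270]`
#' minutes -- so an instantaneous treatment (OTT = 0) falls in the first band.
#' Untreated patients (`NA` OTT) map to `NA`.
#'
#' @param ott Numeric vector of onset-to-treatment times in minutes.
#' @return Factor with levels `"0-90"`, `"91-180"`, `"181-270"`.
#' @export
ott_band <- function(ott) {
  cut(ott, breaks = ott_band_breaks, labels = ott_band_labels,
      include.lowest = TRUE, right = TRUE)
}

#' Simulate a cohort of patient trajectories
#'
#' Samples `n` independent patients through the pathway.  Each patient draws a
#' referral route from the mix, then accumulates the stage delays of that
#' route into an onset-to-door time:
#'
#' * `call_911`: patient delay + responder response + on-scene + transport
#' * `gp`: patient delay + responder response + GP consult + on-scene + transport
#' * `self_referral`: patient delay + self-transport
#' * `in_hospital`: 0 (onset at the door)
#'
#' Treatment requires arrival within `arrival_window`, needle time
#' (door + door-to-needle delay) within `treatment_window`, no intrinsic
#' contraindication and a positive diagnostic work-up (two independent
#' Bernoulli gates).  The caller controls the random stream via `set.seed()`;
#' see [run_replications()] for replication-level seeding.
#'
#' @param config A [pathway_config()].
#' @param n Number of patients, `>= 1`.
#' @return A data.frame with one row per patient: `route`, the sampled stage
#'   delays, `onset_to_door`, `dtn`, `ott` (`NA` if untreated), `treated`,
#'   `band`.
#' @export
simulate_cohort <- function(config, n) {
  stopifnot(inherits(config, "pathway_config"), n >= 1)
  routes <- names(config$route_mix)
  route <- routes[sample.int(4L, n, replace = TRUE, prob = config$route_mix)]

  d <- config$dists
  patient_delay <- dd_sample(d$patient_delay, n)
  responder_response <- dd_sample(d$responder_response, n)
  gp_consult <- dd_sample(d$gp_consult, n)
  on_scene <- dd_sample(d$on_scene, n)
  transport <- dd_sample(d$transport, n)
  self_transport <- dd_sample(d$self_transport, n)
  dtn <- dd_sample(d$dtn, n)

  ems_leg <- responder_response + on_scene + transport
  onset_to_door <- ifelse(route == "call_911", patient_delay + ems_leg,
                   ifelse(route == "gp", patient_delay + gp_consult + ems_leg,
                   ifelse(route == "self_referral", patient_delay + self_transport,
                          0)))
  # stages not on the patient's route do not contribute
  patient_delay[route == "in_hospital"] <- NA_real_
  gp_consult[route != "gp"] <- NA_real_
  responder_response[!route %in% c("gp", "call_911")] <- NA_real_
  on_scene[!route %in% c("gp", "call_911")] <- NA_real_
  transport[!route %in% c("gp", "call_911")] <- NA_real_
  self_transport[route != "self_referral"] <- NA_real_

  needle_time <- onset_to_door + dtn
  time_eligible <- onset_to_door <= config$arrival_window &
    needle_time <= config$treatment_window
  treated <- time_eligible &
    stats::runif(n) >= config$p_contra &
    stats::runif(n) <= config$diagnostic_quality
  ott <- ifelse(treated, needle_time, NA_real_)

  data.frame(route = route,
             patient_delay = patient_delay,
             responder_response = responder_response,
             gp_consult = gp_consult,
             on_scene = on_scene,
             transport = transport,
             self_transport = self_transport,
             onset_to_door = onset_to_door,
             dtn = dtn,
             time_eligible = time_eligible,
             treated = treated,
             ott = ott,
             band = ott_band(ott),
             stringsAsFactors = FALSE)
}

#' Summarise one simulated cohort
#'
#' Aggregates a cohort of trajectories into the per-replication outcome row:
#' IVT rate, mean OTT among treated (`NA` when no one is treated), the
#' fraction arriving within the 4.5 h licence window, the time-eligible
#' fraction, and the treatment-time band shares (conditional on treatment).
#'
#' @param cohort A data.frame from [simulate_cohort()].
#' @param config The [pathway_config()] used to simulate it.
#' @return A one-row data.frame.
#' @export
summarise_cohort <- function(cohort, config) {
  stopifnot(nrow(cohort) >= 1)
  treated <- cohort$treated
  n_treated <- sum(treated)
  shares <- if (n_treated > 0) {
    as.numeric(table(cohort$band[treated])) / n_treated
  } else {
    rep(NA_real_, 3)
  }
  data.frame(
    n_patients = nrow(cohort),
    n_treated = n_treated,
    ivt_rate = mean(treated),
    mean_ott_treated = if (n_treated > 0) mean(cohort$ott[treated]) else NA_real_,
    arrival_within_270 = mean(cohort$onset_to_door <= config$treatment_window),
    time_eligible = mean(cohort$time_eligible),
    band_0_90 = shares[1], band_91_180 = shares[2], band_181_270 = shares[3]
  )
}

#' Run replicated simulation experiments
#'
#' Runs `n_reps` independent replications of an `n_patients` cohort.  Each
#' replication draws from its own substream: a vector of replication seeds is
#' drawn once from `seed`, so results are bit-identical for identical
#' `(seed, n_reps)` and each replication is unaffected by how many others run.
#'
#' @param config A [pathway_config()].
#' @param n_patients Cohort size per replication (default 280, the observed
#'   cohort size).
#' @param n_reps Number of replications, `>= 2`.
#' @param seed Integer seed.
#' @return A data.frame with one row per replication (columns as in
#'   [summarise_cohort()], plus `rep`).
#' @export
run_replications <- function(config, n_patients = 280, n_reps = 1000, seed = 1) {
  stopifnot(n_reps >= 2, n_patients >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    out[[i]] <- summarise_cohort(simulate_cohort(config, n_patients), config)
  }
  res <- do.call(rbind, out)
  res$rep <- seq_len(n_reps)
  res[, c("rep", setdiff(names(res), "rep"))]
}
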