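#' Specification of a synthetic observational cohort
#'
#' Describes a patient-level dataset with the marginal structure of the
#' observed cohort: the referral mix, per-activity median/IQR summaries,
#' the fraction of patients whose onset-to-call time is missing (46%,
#' missing completely at random -- no mechanism was reported), and simple
#' demographic marginals (age ~ Normal(70, 14), 56% male) carried for realism
#' only; the trajectory model never uses them.  In-hospital-onset patients
#' have no prehospital stages, and only EMS-referred patients (GP and 911
#' routes, 76% together) carry ambulance legs.  All times are minutes from
#' symptom onset or stage start; no calendar timestamps are generated.
#'
#' @param n_patients Cohort size (default 280).
#' @param route_mix Named referral mix (default [baseline_route_mix()]).
#' @param activities Data.frame of per-activity quantile summaries
#'   (default [activity_quantiles()]).
#' @param diagnostics Data.frame of intrahospital diagnostic summaries
#'   (default [diagnostic_quantiles()]).
#' @param onset_missing_rate Fraction of onset-to-call times set missing.
#' @param age_mean,age_sd,p_male Demographic marginals.
#' @return A list of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_patients = 280,
                              route_mix = baseline_route_mix(),
                              activities = activity_quantiles(),
                              diagnostics = diagnostic_quantiles(),
                              onset_missing_rate = 0.46,
                              age_mean = 70, age_sd = 14, p_male = 0.56) {
  stopifnot(n_patients >= 1,
            onset_missing_rate >= 0, onset_missing_rate <= 1,
            abs(sum(route_mix) - 1) < 1e-9)
  structure(list(n_patients = n_patients, route_mix = route_mix,
                 activities = activities, diagnostics = diagnostics,
                 onset_missing_rate = onset_missing_rate,
                 age_mean = age_mean, age_sd = age_sd, p_male = p_male),
            class = "synth_cohort_spec")
}

synth_dist <- function(spec, activity) {
  row <- spec$activities[spec$activities$activity == activity, ]
  if (nrow(row) == 0) row <- spec$diagnostics[spec$diagnostics$activity == activity, ]
  stopifnot(nrow(row) == 1)
  fit_quantiles(row$median, row$q1, row$q3)
}

#' Generate a synthetic patient-level cohort
#'
#' One record per patient.  Prehospital fields are populated according to the
#' route (ambulance legs for GP and 911 referrals, a self-transport leg for
#' self-referrals, nothing for in-hospital onset); intrahospital diagnostic
#' times and the door-to-needle time are drawn for every patient who reaches
#' the door.  Onset-to-call values are deleted completely at random at the
#' specified rate.  Reproducible from `seed`.
#'
#' @param spec A [synth_cohort_spec()].
#' @param seed Integer seed.
#' @return A data.frame with columns `patient_id`, `age`, `male`, `route`,
#'   `onset_to_call`, `responder_response`, `gp_consult`, `on_scene`,
#'   `transport`, `self_transport`, `neuro_exam`, `ct_exam`, `lab_exam`,
#'   `dtn`, `ems_transported`.
#' @export
synth_cohort <- function(spec = synth_cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  set.seed(seed)
  n <- spec$n_patients
  routes <- names(spec$route_mix)
  route <- routes[sample.int(length(routes), n, replace = TRUE,
                             prob = spec$route_mix)]
  draw <- function(activity) dd_sample(synth_dist(spec, activity), n)

  onset_to_call <- draw("patient_delay")
  responder_response <- draw("responder_response")
  gp_consult <- draw("gp_consult")
  on_scene <- draw("on_scene")
  transport <- draw("transport")
  self_transport <- draw("self_transport")
  neuro_exam <- draw("neuro_exam")
  ct_exam <- draw("ct_exam")
  lab_exam <- draw("lab_exam")
  dtn <- draw("dtn")

  ems <- route %in% c("gp", "call_911")
  inh <- route == "in_hospital"
  onset_to_call[inh] <- NA_real_
  gp_consult[route != "gp"] <- NA_real_
  responder_response[!ems] <- NA_real_
  on_scene[!ems] <- NA_real_
  transport[!ems] <- NA_real_
  self_transport[route != "self_referral"] <- NA_real_
  # MCAR missingness on the observed onset-to-call times
  miss <- !inh & stats::runif(n) < spec$onset_missing_rate
  onset_to_call[miss] <- NA_real_

  data.frame(
    patient_id = seq_len(n),
    age = round(stats::rnorm(n, spec$age_mean, spec$age_sd)),
    male = stats::runif(n) < spec$p_male,
    route = route,
    onset_to_call = onset_to_call,
    responder_response = responder_response,
    gp_consult = gp_consult,
    on_scene = on_scene,
    transport = transport,
    self_transport = self_transport,
    neuro_exam = neuro_exam,
    ct_exam = ct_exam,
    lab_exam = lab_exam,
    dtn = dtn,
    ems_transported = ems,
    stringsAsFactors = FALSE
  )
}

med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Summarise a cohort in the published descriptive layout
#'
#' Computes the descriptive statistics the observational study reported:
#' cohort size, demographics, onset-to-call availability and median/IQR,
#' referral-mode percentages, EMS-transported percentage, and median/IQR of
#' each activity duration.  Invariant to row order.
#'
#' @param cohort A data.frame from [synth_cohort()].
#' @return A data.frame with columns `statistic`, `value`, `q1`, `q3`.
#' @export
describe_cohort <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0) stop("empty cohort")
  n <- nrow(cohort)
  rt <- function(r) 100 * mean(cohort$route == r)
  rows <- list(
    c("n_patients", n, NA, NA),
    c("age_mean", mean(cohort$age), stats::sd(cohort$age), NA),
    c("male_pct", 100 * mean(cohort$male), NA, NA),
    c("onset_to_call_valid_pct", 100 * mean(!is.na(cohort$onset_to_call)), NA, NA),
    c("onset_to_call", med_iqr(cohort$onset_to_call)),
    c("route_gp_pct", rt("gp"), NA, NA),
    c("route_911_pct", rt("call_911"), NA, NA),
    c("route_self_pct", rt("self_referral"), NA, NA),
    c("route_in_hospital_pct", rt("in_hospital"), NA, NA),
    c("ems_transported_pct", 100 * mean(cohort$ems_transported), NA, NA),
    c("responder_response", med_iqr(cohort$responder_response)),
    c("on_scene", med_iqr(cohort$on_scene)),
    c("transport", med_iqr(cohort$transport)),
    c("neuro_exam", med_iqr(cohort$neuro_exam)),
    c("ct_exam", med_iqr(cohort$ct_exam)),
    c("lab_exam", med_iqr(cohort$lab_exam)),
    c("dtn", med_iqr(cohort$dtn))
  )
  out <- data.frame(
    statistic = vapply(rows, function(r) as.character(r[1]), ""),
    value = vapply(rows, function(r) as.numeric(r[2]), 0),
    q1 = vapply(rows, function(r) as.numeric(r[3]), 0),
    q3 = vapply(rows, function(r) as.numeric(r[4]), 0),
    stringsAsFactors = FALSE
  )
  out
}

#' Refit activity distributions from a patient-level cohort
#'
#' Closes the loop between the synthetic-data generator and the fitting
#' pipeline: computes each activity's empirical median/IQR from a cohort
#' table and refits [fit_quantiles()] distributions, as one would from an
#' observational dataset.
#'
#' @param cohort A data.frame from [synth_cohort()].
#' @return Named list of [duration_dist()] for the trajectory-model stages.
#' @export
fit_cohort_distributions <- function(cohort) {
  stages <- c(patient_delay = "onset_to_call",
              responder_response = "responder_response",
              gp_consult = "gp_consult",
              on_scene = "on_scene",
              transport = "transport",
              self_transport = "self_transport",
              dtn = "dtn")
  out <- lapply(stages, function(col) {
    s <- med_iqr(cohort[[col]])
    fit_quantiles(s[["median"]], s[["q1"]], s[["q3"]])
  })
  names(out) <- names(stages)
  out
}
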