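# shared fixtures, built in code

# a config in which every stage is a point mass (deterministic trajectories)
point_config <- function(medians = c(patient_delay = 41, responder_response = 9,
                                     gp_consult = 30, on_scene = 20,
                                     transport = 17, self_transport = 17,
                                     dtn = 35),
                         route_mix = baseline_route_mix(),
                         p_contra = 0, diagnostic_quality = 1, ...) {
  dists <- lapply(medians, function(v) duration_dist("point_mass", value = v))
  pathway_config(route_mix, dists, p_contra = p_contra,
                 diagnostic_quality = diagnostic_quality, ...)
}

# force every patient onto one route
one_route_mix <- function(route) {
  mix <- c(gp = 0, call_911 = 0, self_referral = 0, in_hospital = 0)
  mix[route] <- 1
  mix
}

# observed activity summaries (rows used all over the tests)
observed_rows <- function() {
  aq <- activity_quantiles()
  aq[aq$observed, ]
}
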