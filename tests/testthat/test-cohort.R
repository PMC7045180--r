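test_that("deterministic trajectories compose stage delays per route", {
  # all delays at the observed medians, everyone via 911:
  # door = 41 + 9 + 20 + 17 = 87, needle = 87 + 35 = 122, middle band
  cfg <- point_config(route_mix = one_route_mix("call_911"))
  set.seed(1)
  coh <- simulate_cohort(cfg, 50)
  expect_true(all(coh$route == "call_911"))
  expect_true(all(coh$onset_to_door == 87))
  expect_true(all(coh$treated))
  expect_true(all(coh$ott == 122))
  expect_true(all(coh$band == "91-180"))
  expect_true(all(is.na(coh$gp_consult)))

  # GP route adds the consult stage: door = 87 + 30 = 117, needle = 152
  cfg_gp <- point_config(route_mix = one_route_mix("gp"))
  set.seed(1)
  expect_true(all(simulate_cohort(cfg_gp, 20)$ott == 152))

  # zero-delay limit: instantaneous treatment in the first band
  cfg0 <- point_config(medians = setNames(rep(0, 7), names(point_config()$dists)),
                       route_mix = one_route_mix("call_911"))
  set.seed(1)
  coh0 <- simulate_cohort(cfg0, 20)
  expect_true(all(coh0$ott == 0))
  expect_true(all(coh0$band == "0-90"))

  # a patient delay beyond the arrival window is never treated
  cfg_late <- point_config(medians = c(patient_delay = 250, responder_response = 0,
                                       gp_consult = 0, on_scene = 0, transport = 0,
                                       self_transport = 0, dtn = 0),
                           route_mix = one_route_mix("self_referral"))
  set.seed(1)
  late <- simulate_cohort(cfg_late, 20)
  expect_false(any(late$treated))
  expect_true(all(is.na(late$band)))
})

test_that("eligibility gates behave as a two-window rule plus Bernoulli gates", {
  # arrival window binds even when the needle would be in time
  cfg <- point_config(medians = c(patient_delay = 245, responder_response = 0,
                                  gp_consult = 0, on_scene = 0, transport = 0,
                                  self_transport = 0, dtn = 0),
                      route_mix = one_route_mix("self_referral"))
  set.seed(1)
  expect_false(any(simulate_cohort(cfg, 10)$treated))
  # needle window binds even with a timely arrival
  cfg2 <- point_config(medians = c(patient_delay = 230, responder_response = 0,
                                   gp_consult = 0, on_scene = 0, transport = 0,
                                   self_transport = 0, dtn = 50),
                       route_mix = one_route_mix("self_referral"))
  set.seed(1)
  expect_false(any(simulate_cohort(cfg2, 10)$treated))
  # p_contra = 1 blocks everyone; the mean OTT is then undefined
  cfg3 <- point_config(route_mix = one_route_mix("call_911"), p_contra = 1)
  set.seed(1)
  r <- summarise_cohort(simulate_cohort(cfg3, 100), cfg3)
  expect_equal(r$ivt_rate, 0)
  expect_true(is.na(r$mean_ott_treated))
  expect_true(is.na(r$band_0_90))
})

test_that("zero-delay limit of the replication engine gives ivt_rate = 1 - p_contra", {
  cfg <- point_config(medians = setNames(rep(0, 7), names(point_config()$dists)),
                      p_contra = 0.023)
  reps <- run_replications(cfg, n_patients = 280, n_reps = 200, seed = 5)
  expect_equal(mean(reps$ivt_rate), 1 - 0.023, tolerance = 0.01)
  expect_true(all(reps$mean_ott_treated == 0))
})

test_that("replication runs are reproducible and statistically well-behaved", {
  cfg <- baseline_config()
  a <- run_replications(cfg, 100, 20, seed = 9)
  b <- run_replications(cfg, 100, 20, seed = 9)
  expect_identical(a, b)

  # CI width shrinks like 1/sqrt(R) as replications double (CLT)
  big <- run_replications(cfg, 100, 400, seed = 10)
  w <- function(x) { ci <- mc_confidence_interval(x); ci[["hi"]] - ci[["lo"]] }
  ratio <- w(big$ivt_rate[1:200]) / w(big$ivt_rate)
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 1.75)

  # band shares are a distribution over treated patients
  shares <- a[a$n_treated > 0, c("band_0_90", "band_91_180", "band_181_270")]
  expect_equal(unname(rowSums(shares)), rep(1, nrow(shares)))
  # treated implies time-eligible
  expect_true(all(a$ivt_rate <= a$time_eligible))
})

test_that("stochastically smaller delays never reduce the treatment rate", {
  cfg <- baseline_config()
  faster <- cfg
  faster$dists$patient_delay <- dd_truncate(cfg$dists$patient_delay, 60)
  slowrate <- mean(run_replications(cfg, 280, 200, seed = 21)$ivt_rate)
  fastrate <- mean(run_replications(faster, 280, 200, seed = 21)$ivt_rate)
  expect_gte(fastrate, slowrate)

  down <- cfg
  down$dists$dtn <- dd_scale_median(cfg$dists$dtn, 20)
  expect_gte(mean(run_replications(down, 280, 200, seed = 22)$ivt_rate), slowrate)
})
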