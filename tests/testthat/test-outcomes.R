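test_that("replication confidence intervals follow the normal approximation", {
  expect_equal(unname(mc_confidence_interval(rep(0.218, 50))),
               c(0.218, 0.218, 0.218))
  expect_error(mc_confidence_interval(0.5), "at least 2")

  # CLT oracle: cohort-level binomial means recover the true rate
  set.seed(101)
  cohorts <- rbinom(1e4, 280, 0.218) / 280
  ci <- mc_confidence_interval(cohorts)
  expect_gt(ci[["mean"]], 0.213); expect_lt(ci[["mean"]], 0.223)
  expect_true(ci[["lo"]] < ci[["mean"]] && ci[["mean"]] < ci[["hi"]])
  # width scales as 1/sqrt(R)
  w <- function(x) { c <- mc_confidence_interval(x); c[["hi"]] - c[["lo"]] }
  expect_equal(w(cohorts[1:2500]) / w(cohorts), 2, tolerance = 0.1)
})

test_that("attributable excellent outcome reproduces the published column", {
  # spot values from the published grid
  expect_equal(attributable_mrs01(c(0.170, 0.709, 0.121)), 12.5)
  expect_equal(attributable_mrs01(c(0.689, 0.263, 0.048)), 18.6)
  expect_equal(attributable_mrs01(c(0.860, 0.113, 0.027)), 20.6)
  expect_equal(attributable_mrs01(c(1, 0, 0)), 22.2)
  # bounded by the extreme band coefficients
  coeff <- benefit_coefficients()
  set.seed(5)
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 100, runif(3))) / 100
    v <- attributable_mrs01(p, digits = NULL)
    expect_gte(v, 100 * min(coeff$band_benefit) - 1e-9)
    expect_lte(v, 100 * max(coeff$band_benefit) + 1e-9)
  }
  expect_error(attributable_mrs01(c(0.5, 0.2, 0.2)), "sum to 1")
  # coefficients must decline with treatment delay
  expect_error(benefit_coefficients(band_benefit = c(0.1, 0.2, 0.05)))
})

test_that("healthy-days benefit is linear in the OTT reduction", {
  expect_equal(extra_healthy_days(129, 129), 0)
  expect_equal(extra_healthy_days(129, 110), 34.2)  # published rounds to 34.4
  expect_equal(extra_healthy_days(100, 130), -54)   # worsening goes negative
  # slope recovery from the published grid: regress extra days on OTT saved
  ref <- reference_results()
  dott <- ref$ott[ref$scenario == "0"] - ref$ott
  keep <- ref$scenario != "0"
  slope <- coef(lm(ref$extra_days[keep] ~ 0 + dott[keep]))[[1]]
  expect_gt(slope, 1.6); expect_lt(slope, 1.9)
})

test_that("chi-squared comparison matches the brute-force Pearson sum", {
  r <- chi_square_2x2(50, 100, 50, 100)
  expect_equal(unname(r), c(0, 1))
  # a scenario-11-sized rate shift on n = 280 is significant
  expect_lt(chi_square_2x2(61, 280, 116, 280)[["p"]], 0.05)
  # oracle: direct sum of (O-E)^2/E over the four cells
  brute <- function(k1, n1, k2, n2) {
    o <- c(k1, n1 - k1, k2, n2 - k2)
    rs <- c(k1 + k2, n1 + n2 - k1 - k2)
    cs <- c(n1, n2)
    e <- c(rs[1] * cs[1], rs[2] * cs[1], rs[1] * cs[2], rs[2] * cs[2]) / (n1 + n2)
    sum((o - e)^2 / e)
  }
  set.seed(202)
  for (i in 1:25) {
    n1 <- sample(5:300, 1); n2 <- sample(5:300, 1)
    k1 <- rbinom(1, n1, runif(1, 0.1, 0.9)); k2 <- rbinom(1, n2, runif(1, 0.1, 0.9))
    if ((k1 + k2) %in% c(0, n1 + n2)) next
    expect_equal(chi_square_2x2(k1, n1, k2, n2)[["statistic"]],
                 brute(k1, n1, k2, n2))
  }
  expect_error(chi_square_2x2(0, 10, 0, 20), "empty margin")
})

test_that("the results table aggregates scenarios against the baseline row", {
  base <- point_config(route_mix = one_route_mix("call_911"), p_contra = 0.023)
  s <- builtin_scenarios()
  rows <- list(
    evaluate_scenario(base, s[["0"]], n_patients = 50, n_reps = 40, seed = 1),
    evaluate_scenario(base, s[["8D"]], n_patients = 50, n_reps = 40, seed = 2))
  tab <- results_table(rows, n_patients = 280)
  expect_identical(tab$scenario, c("0", "8D"))        # input order kept
  expect_true(is.na(tab$extra_days[1]))               # baseline has no delta
  # deterministic delays: OTT drops from 122 to 87 when the needle is instant
  expect_equal(tab$ott, c(122, 87))
  expect_equal(tab$extra_days[2], 1.8 * 35)
  expect_false(any(tab$sig_vs_baseline[1]))

  # baseline alone is a valid single-row table
  solo <- results_table(rows[1], n_patients = 280)
  expect_identical(nrow(solo), 1L)
  expect_true(is.na(solo$extra_days))

  # full-precision round trip through JSON
  path <- tempfile(fileext = ".json")
  write_results_table(tab, path)
  back <- read_results_table(path)
  expect_equal(back$ivt_rate, tab$ivt_rate, tolerance = 0)
  expect_equal(back$ott, tab$ott, tolerance = 0)
  csv <- tempfile(fileext = ".csv")
  write_results_table(tab, csv)
  expect_equal(read_results_table(csv)$scenario, tab$scenario)
})
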