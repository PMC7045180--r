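test_that("closed-form quantile fit matches the two-quantile formulas", {
  # door-to-needle summary 35 (25-45): location = log(35), spread from IQR
  d <- fit_quantiles(35, 25, 45)
  expect_equal(d$meanlog, log(35))
  expect_equal(d$meanlog, 3.5553, tolerance = 1e-4)
  expect_equal(d$sdlog, (log(45) - log(25)) / (2 * qnorm(0.75)))
  expect_equal(d$sdlog, 0.4357, tolerance = 1e-4)
  # degenerate IQR collapses to a point mass
  pm <- fit_quantiles(10, 10, 10)
  expect_identical(pm$family, "point_mass")
  expect_equal(pm$value, 10)
  # invalid summaries are rejected
  expect_error(fit_quantiles(10, 12, 20), "invalid")
  expect_error(fit_quantiles(10, -1, 20), "invalid")
  expect_error(fit_quantiles(10, 5, 8), "invalid")
  expect_error(fit_quantiles(0, 0, 5), "median > 0")
})

test_that("fit residuals are reported for log-asymmetric summaries", {
  d <- fit_quantiles(41, 5, 130)
  fit <- attr(d, "fit")
  # median anchored exactly, quartile ratio preserved exactly
  expect_equal(dd_median(d), 41)
  fq <- dd_quartiles(d)
  expect_equal(fq[["q3"]] / fq[["q1"]], 130 / 5, tolerance = 1e-10)
  # the asymmetric endpoints themselves cannot both be matched; residuals say so
  expect_gt(fit$residual[["q1"]], 0.5)
  expect_gt(fit$residual[["q3"]], 0.5)
})

test_that("sampling round-trip recovers median and quartile ratio for every observed summary", {
  rows <- observed_rows()
  for (i in seq_len(nrow(rows))) {
    d <- fit_quantiles(rows$median[i], rows$q1[i], rows$q3[i])
    set.seed(100 + i)
    x <- dd_sample(d, 5e5)
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    expect_lt(abs(q[2] / rows$median[i] - 1), 0.02)
    fitted_ratio <- dd_quartiles(d)[["q3"]] / dd_quartiles(d)[["q1"]]
    expect_lt(abs((q[3] / q[1]) / fitted_ratio - 1), 0.02)
  }
  # where the printed IQR is symmetric on the log scale the full summary
  # round-trips: response time 9 (7-12) has sqrt(7*12) = 9.17, within 2% of 9
  d <- fit_quantiles(9, 7, 12)
  set.seed(7)
  q <- quantile(dd_sample(d, 5e5), c(0.25, 0.75), names = FALSE)
  expect_lt(abs(q[1] / 7 - 1), 0.025)
  expect_lt(abs(q[2] / 12 - 1), 0.025)
})

test_that("median rescaling shifts location and preserves relative dispersion", {
  d <- fit_quantiles(41, 5, 130)
  s <- dd_scale_median(d, 15)
  expect_equal(dd_median(s), 15)
  expect_equal(s$sdlog, d$sdlog)                      # spread untouched
  q0 <- dd_quartiles(d); q1 <- dd_quartiles(s)
  expect_equal(q1[["q3"]] / q1[["q1"]], q0[["q3"]] / q0[["q1"]])
  # sampling check of the same property
  set.seed(1)
  x <- dd_sample(s, 2e5)
  expect_lt(abs(median(x) / 15 - 1), 0.02)
  # identity and degenerate limits
  expect_equal(dd_scale_median(d, 41), d, ignore_attr = "fit")
  z <- dd_scale_median(d, 0)
  expect_identical(z$family, "point_mass")
  expect_identical(dd_sample(z, 5), rep(0, 5))
  expect_error(dd_scale_median(d, -3), ">= 0")
})

test_that("truncation is a hard cap: mass accumulates, mean never increases", {
  d <- fit_quantiles(20, 15, 25)
  capped <- dd_truncate(d, 15)
  set.seed(2)
  x <- dd_sample(capped, 1e5)
  expect_true(all(x <= 15))
  # capping exactly at the median leaves half the mass at the cap
  at_med <- dd_truncate(d, 20)
  set.seed(3)
  y <- dd_sample(at_med, 1e5)
  expect_equal(mean(y == 20), 0.5, tolerance = 0.01)
  expect_lte(mean(y), mean(dd_sample(d, 1e5)))
  # a cap beyond the 99.9th percentile is statistically inert
  hi <- qlnorm(0.999, d$meanlog, d$sdlog)
  set.seed(4)
  a <- dd_sample(d, 1e5)
  set.seed(4)
  b <- dd_sample(dd_truncate(d, hi * 1.01), 1e5)
  expect_lt(suppressWarnings(ks.test(a, b)$statistic), 0.01)
  # infinite cap is the identity, non-positive caps are rejected
  expect_equal(dd_truncate(d, Inf), d)
  expect_error(dd_truncate(d, 0), "cap")
})

test_that("sampling is reproducible and always non-negative", {
  d <- duration_dist("lognormal", meanlog = 3.5553, sdlog = 0.4357)
  set.seed(11); a <- dd_sample(d, 1000)
  set.seed(11); b <- dd_sample(d, 1000)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  set.seed(12)
  expect_equal(median(dd_sample(d, 1e6)), 35, tolerance = 0.2 / 35)
  expect_identical(dd_sample(duration_dist("point_mass", value = 0), 5),
                   rep(0, 5))
})

test_that("distribution libraries round-trip through JSON", {
  dists <- list(dtn = fit_quantiles(35, 25, 45),
                on_scene = dd_truncate(fit_quantiles(20, 15, 25), 15),
                none = duration_dist("point_mass", value = 0))
  path <- tempfile(fileext = ".json")
  write_distribution_library(dists, path)
  back <- read_distribution_library(path)
  expect_identical(names(back), names(dists))
  for (nm in names(dists)) {
    expect_equal(dd_quartiles(back[[nm]]), dd_quartiles(dists[[nm]]))
    expect_equal(back[[nm]]$cap, dists[[nm]]$cap)
  }
  # the packaged baseline library reproduces the observed summaries
  lib <- read_distribution_library(
    system.file("extdata", "activity_distributions.json", package = "strokesim"))
  rows <- observed_rows()
  for (i in seq_len(nrow(rows))) {
    expect_equal(dd_median(lib[[rows$activity[i]]]), rows$median[i])
  }
})
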