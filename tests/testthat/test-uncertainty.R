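# Uncertainty propagation: exact, delta and MVN routes.

test_that("exact exponential uncertainty: constant hazard variance, Eq-style means", {
  f <- fit_exponential_exact(toy_data())     # rate 0.3, 3 events
  g <- time_grid(c(0.1, 1, 10, 100), observed_end = 100)
  res <- exact_exponential_uncertainty(f, g)
  expect_equal(res$hazard$se, rep(sqrt(0.03), 4))
  expect_equal(diff(range(res$hazard$upper - res$hazard$lower)), 0)
  expect_equal(res$mean$point, 1 / 0.3)
  expect_equal(res$mean$se^2, 1 / (0.3^2 * 3), tolerance = 1e-12)  # 3.7037
  expect_error(exact_exponential_uncertainty(
    fit_parametric(flat_d400(), "weibull"), g),
    class = "hazext_usage_error")
})

test_that("delta method: linear functionals are exact, exponential hazard matches", {
  f <- fit_exponential_exact(toy_data())
  # identity functional on the estimation scale picks out vcov[1,1]
  expect_equal(delta_variance(f, function(fp) log(fp$params$rate)),
               unname(f$vcov[1, 1]), tolerance = 1e-8)
  for (t in c(0.2, 5, 50)) {
    expect_equal(delta_variance(f, function(fp) haz(fp, t)), 0.03,
                 tolerance = 1e-8)
  }
})

test_that("delta and MVN agree for a Weibull hazard (large-B oracle)", {
  # At n = 400 the extrapolated log-hazard SE is large enough that the MVN
  # variance carries visible second-order terms the linearisation drops, so
  # the two routes are compared at the accuracy the linearisation supports.
  fit <- fit_parametric(increasing_d400(), "weibull")
  vd <- delta_variance(fit, function(fp) haz(fp, 2))
  draws <- mvn_parameter_draws(fit, 2e4, seed = 12)
  hz <- apply(draws, 1, function(e)
    haz(hazext:::from_estimation("weibull", e), 2))
  vm <- mean((hz - haz(fit$fp, 2))^2)
  expect_equal(sqrt(vd), sqrt(vm), tolerance = 0.05)
})

test_that("MVN curves: degenerate vcov gives zero-width bands", {
  f0 <- fit_with_vcov(fit_exponential_exact(toy_data()),
                      matrix(0, 1, 1, dimnames = list("log(rate)",
                                                      "log(rate)")))
  cv <- mvn_curve(f0, "hazard", time_grid(c(0.5, 1, 2)), B = 200, seed = 1)
  expect_equal(cv$se, rep(0, 3))
  expect_equal(cv$lower, cv$upper)
  expect_equal(cv$lower, cv$point)
  # and EVPI downstream of a degenerate PSA is exactly zero (see cea tests)
})

test_that("MVN draws and curves are seed-reproducible and domain-respecting", {
  fit <- fit_parametric(increasing_d400(), "gompertz")
  d1 <- mvn_parameter_draws(fit, 50, seed = 5)
  d2 <- mvn_parameter_draws(fit, 50, seed = 5)
  expect_identical(d1, d2)
  g <- time_grid(seq(0.1, 4, by = 0.26), observed_end = 1)
  cs <- mvn_curve(fit, "survival", g, B = 400, seed = 5)
  expect_true(all(cs$lower >= 0 & cs$upper <= 1))
  expect_true(all(cs$lower <= cs$point & cs$point <= cs$upper))
  ch <- mvn_curve(fit, "hazard", g, B = 400, seed = 5)
  expect_true(all(ch$lower >= 0))
})

test_that("mean survival: exact closed form, MVN convergence and coherence", {
  fe <- fit_exponential_exact(flat_d400())
  me <- mean_survival(fe, Inf, method = "exact")
  expect_equal(me$point, 1 / fe$fp$params$rate)
  expect_equal(me$se, sqrt(1 / (fe$fp$params$rate^2 * fe$n_events)))

  fit <- fit_parametric(increasing_d400(), "weibull")
  m_small <- mean_survival(fit, 10, "mvn", B = 500, seed = 2)
  m_large <- mean_survival(fit, 10, "mvn", B = 1e4, seed = 3)
  expect_lt(abs(m_small$se - m_large$se) / m_large$se, 0.10)
  expect_true(m_small$lower <= m_small$point & m_small$point <= m_small$upper)

  # coherence: the mean-survival SE is exactly the one induced by the same
  # seeded parameter draws, and each draw's mean equals the quadrature of
  # that draw's survival curve
  draws <- mvn_parameter_draws(fit, 500, seed = 2)
  vals <- apply(draws, 1, function(e)
    rmst(hazext:::from_estimation("weibull", e), 10))
  expect_equal(m_small$se, sqrt(mean((vals - m_small$point)^2)),
               tolerance = 1e-12)
  for (b in c(3, 101, 400)) {
    fpb <- hazext:::from_estimation("weibull", draws[b, ])
    expect_equal(vals[b],
                 stats::integrate(function(u) surv(fpb, u), 0, 10,
                                  abs.tol = 1e-10)$value,
                 tolerance = 1e-6)
  }
})

test_that("delta mean survival propagates the diverging-mean error", {
  d <- increasing_d400()
  fit <- fit_parametric(d, "gompertz")
  if (fit$fp$params$shape < 0) {
    expect_error(mean_survival(fit, Inf, "delta"),
                 class = "hazext_diverging_mean_error")
  }
  expect_error(mean_survival(fit_parametric(d, "loglogistic"), Inf, "exact"),
               class = "hazext_usage_error")
})

test_that("band transforms: round trips, invariance, domain errors", {
  # logit(0.5) = 0 and the round trip is the identity
  expect_equal(stats::qlogis(0.5), 0)
  fit <- fit_parametric(flat_d400(), "weibull")
  g <- time_grid(seq(0.2, 3, by = 0.2), observed_end = 1)
  cv <- mvn_curve(fit, "hazard", g, B = 300, seed = 9)
  cv2 <- band_transform(cv, "log")     # percentile bands: unchanged
  expect_equal(cv2$lower, cv$lower)
  expect_equal(cv2$upper, cv$upper)

  dl <- delta_curve(fit, "hazard", g, transform = "log")
  expect_true(all(dl$lower > 0))
  expect_true(all(dl$lower <= dl$point & dl$point <= dl$upper))
  ds <- delta_curve(fit, "survival", g, transform = "logit")
  expect_true(all(ds$lower >= 0 & ds$upper <= 1))

  # normal-approximation log-band approximates the percentile band when the
  # draw distribution is near log-normal
  cvL <- mvn_curve(fit, "hazard", g, B = 1e4, seed = 10)
  dlL <- delta_curve(fit, "hazard", g, transform = "log")
  expect_equal(dlL$lower, cvL$lower, tolerance = 0.06)
  expect_equal(dlL$upper, cvL$upper, tolerance = 0.06)

  bad <- cv; bad$point[1] <- 0
  attr(bad, "method") <- "delta"
  expect_error(band_transform(bad, "log"), class = "hazext_domain_error")
})

test_that("tidy curve export marks the extrapolated period", {
  fit <- fit_exponential_exact(flat_d400())
  g <- time_grid(seq(0.5, 4, by = 0.5), observed_end = 1)
  cv <- mvn_curve(fit, "hazard", g, B = 200, seed = 4)
  df <- tidy_curves(cv)
  expect_equal(df$extrapolated, df$time > 1)
  expect_named(df, c("time", "quantity", "method", "point", "se", "lower",
                     "upper", "extrapolated"))
  tf <- tempfile(fileext = ".csv")
  tidy_curves(list(cv), tf)
  expect_equal(nrow(utils::read.csv(tf)), 8)
})
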