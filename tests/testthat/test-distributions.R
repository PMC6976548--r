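# Seven-family distribution layer: identities, limits, nesting, sampling.

test_that("survival boundary behaviour and closed-form values", {
  expect_equal(surv(family_params("exponential", rate = log(2)), 1), 0.5)
  for (fam in SURVIVAL_FAMILIES) {
    set.seed(11)
    fp <- random_fp(fam)
    expect_equal(surv(fp, 0), 1)
    expect_equal(cumhaz(fp, 0), 0)
    s <- surv(fp, seq(0.01, 6, length.out = 40))
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("H(t) = -log S(t) across families, parameters and times", {
  set.seed(42)
  times <- seq(0.02, 5, length.out = 20)
  for (fam in SURVIVAL_FAMILIES) {
    for (r in 1:10) {
      fp <- random_fp(fam)
      s <- surv(fp, times)
      ok <- s > 1e-12          # below this, log S underflows in double
      expect_lt(max(abs(cumhaz(fp, times)[ok] + log(s[ok]))), 1e-8)
    }
  }
})

test_that("generalised-gamma survival matches quadrature of its hazard", {
  fp <- family_params("gengamma", mu = -0.5 * 0 + 0.2, sigma = 0.8, Q = -0.5)
  Hq <- stats::integrate(function(u) haz(fp, u), 0, 1.3,
                         abs.tol = 1e-12, rel.tol = 1e-12)$value
  expect_equal(surv(fp, 1.3), exp(-Hq), tolerance = 1e-8)
})

test_that("hazard equals -d/dt log S (finite-difference oracle)", {
  expect_equal(haz(family_params("exponential", rate = 1.16), c(0.3, 7)),
               c(1.16, 1.16))
  expect_equal(haz(family_params("weibull", shape = 1, rate = 2), 0.7), 2)
  ll <- family_params("loglogistic", shape = 2, rate = 1.5)
  expect_equal(haz(ll, 0.9), haz_fd(ll, 0.9), tolerance = 1e-6)
  set.seed(7)
  for (fam in SURVIVAL_FAMILIES) {
    fp <- random_fp(fam)
    for (t in c(0.4, 1.7)) {
      expect_equal(haz(fp, t), haz_fd(fp, t), tolerance = 1e-5)
    }
  }
})

test_that("hazard at t = 0 returns finite limits and errors on divergence", {
  expect_equal(haz(family_params("lognormal", meanlog = 0, sdlog = 1), 0), 0)
  expect_equal(haz(family_params("weibull", shape = 2, rate = 1), 0), 0)
  expect_equal(haz(family_params("gompertz", shape = -0.3, rate = 0.8), 0), 0.8)
  expect_error(haz(family_params("weibull", shape = 0.7, rate = 1), 0),
               class = "hazext_domain_error")
  expect_error(haz(family_params("gamma", shape = 0.5, rate = 1), 0),
               class = "hazext_domain_error")
})

test_that("log-density equals log h + log S; f = h * S pointwise", {
  expect_equal(logdens(family_params("exponential", rate = 1), 2), -2)
  expect_equal(logdens(family_params("lognormal", meanlog = 0, sdlog = 1), 1),
               log(1 / sqrt(2 * pi)))
  set.seed(13)
  times <- c(0.1, 0.8, 2.5)
  for (fam in SURVIVAL_FAMILIES) {
    fp <- random_fp(fam)
    expect_lt(max(abs(exp(logdens(fp, times)) -
                        haz(fp, times) * surv(fp, times))), 1e-10)
  }
})

test_that("cumulative hazard closed forms and identities", {
  expect_equal(cumhaz(family_params("exponential", rate = 1.16), 2), 2.32)
  expect_equal(cumhaz(family_params("gompertz", shape = 0, rate = 0.5), 3), 1.5)
  expect_equal(cumhaz(family_params("gompertz", shape = 1e-9, rate = 0.5), 3),
               1.5, tolerance = 1e-6)
  g <- family_params("gamma", shape = 2, rate = 3)
  expect_equal(cumhaz(g, 0.4), -log(surv(g, 0.4)), tolerance = 1e-10)
})

test_that("nested families reduce exactly; gengamma limits hold", {
  t <- seq(0.05, 4, length.out = 25)
  ex <- family_params("exponential", rate = 1.3)
  expect_equal(surv(family_params("weibull", shape = 1, rate = 1.3), t),
               surv(ex, t), tolerance = 1e-12)
  expect_equal(surv(family_params("gamma", shape = 1, rate = 1.3), t),
               surv(ex, t), tolerance = 1e-12)
  expect_equal(surv(family_params("gompertz", shape = 0, rate = 1.3), t),
               surv(ex, t), tolerance = 1e-12)
  # gengamma Q = 1 is a Weibull with shape 1/sigma and rate exp(-mu/sigma)
  gg1 <- family_params("gengamma", mu = 0.4, sigma = 0.5, Q = 1)
  wb <- family_params("weibull", shape = 2, rate = exp(-0.4 / 0.5))
  expect_equal(haz(gg1, t), haz(wb, t), tolerance = 1e-10)
  # Q -> 0 approaches the log-normal hazard
  gg0 <- family_params("gengamma", mu = 0.1, sigma = 0.7, Q = 1e-4)
  ln <- family_params("lognormal", meanlog = 0.1, sdlog = 0.7)
  expect_equal(haz(gg0, t), haz(ln, t), tolerance = 1e-3)
})

test_that("sampling is reproducible and matches the analytic distribution", {
  fp <- family_params("weibull", shape = 2, rate = 1)
  expect_identical(rtimes(fp, 5, seed = 3), rtimes(fp, 5, seed = 3))
  x <- rtimes(fp, 1e5, seed = 99)
  ks <- suppressWarnings(stats::ks.test(x, function(q) 1 - surv(fp, q)))$statistic
  expect_lt(ks, 1.63 / sqrt(1e5))   # 1% critical value of the KS statistic
  # gengamma sampler against its own survival function
  gg <- family_params("gengamma", mu = 0.2, sigma = 0.8, Q = -0.5)
  xg <- rtimes(gg, 2e4, seed = 98)
  ksg <- suppressWarnings(stats::ks.test(xg, function(q) 1 - surv(gg, q)))$statistic
  expect_lt(ksg, 1.63 / sqrt(2e4))
  # Gompertz with negative shape has a never-event fraction exp(-rate/|shape|)
  go <- family_params("gompertz", shape = -1, rate = 0.5)
  xgo <- rtimes(go, 2e4, seed = 97)
  expect_equal(mean(is.infinite(xgo)), exp(-0.5), tolerance = 0.02)
})

test_that("restricted mean: closed forms agree with quadrature oracle", {
  set.seed(21)
  for (fam in SURVIVAL_FAMILIES) {
    fp <- random_fp(fam)
    expect_equal(rmst(fp, 10), rmst_quad(fp, 10), tolerance = 1e-6,
                 info = fam)
    # monotone in horizon and bounded by it
    h <- c(0.5, 1, 2, 5, 10)
    v <- vapply(h, function(x) rmst(fp, x), numeric(1))
    expect_true(all(diff(v) >= -1e-10))
    expect_true(all(v > 0 & v <= h))
  }
  expect_equal(rmst(family_params("exponential", rate = 1 / 0.9), Inf), 0.9)
  expect_lt(rmst(family_params("lognormal", meanlog = 0, sdlog = 1), 1e-4),
            1e-3)
})

test_that("diverging unrestricted means are refused with guidance", {
  expect_error(rmst(family_params("gompertz", shape = -0.5, rate = 1), Inf),
               class = "hazext_diverging_mean_error")
  expect_error(rmst(family_params("loglogistic", shape = 0.8, rate = 1), Inf),
               class = "hazext_diverging_mean_error")
  expect_error(rmst(family_params("gengamma", mu = 0, sigma = 2, Q = -1), Inf),
               class = "hazext_diverging_mean_error")
  # but finite horizons still work
  expect_gt(rmst(family_params("gompertz", shape = -0.5, rate = 1), 10), 0)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(family_params("exponential", rate = -1),
               class = "hazext_domain_error")
  expect_error(family_params("weibull", shape = 0, rate = 1),
               class = "hazext_domain_error")
  expect_error(family_params("weibull", shape = 1),
               class = "hazext_domain_error")
  expect_error(family_params("nope", rate = 1))
  expect_error(surv(family_params("exponential", rate = 1), -0.1),
               class = "hazext_domain_error")
})

test_that("distribution layer agrees with flexsurv on shared families", {
  t <- c(0.3, 0.9, 2.1)
  gg <- family_params("gengamma", mu = 0.3, sigma = 0.7, Q = -0.8)
  expect_equal(surv(gg, t),
               flexsurv::pgengamma(t, mu = 0.3, sigma = 0.7, Q = -0.8,
                                   lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(exp(logdens(gg, t)),
               flexsurv::dgengamma(t, mu = 0.3, sigma = 0.7, Q = -0.8),
               tolerance = 1e-10)
  go <- family_params("gompertz", shape = -0.4, rate = 1.2)
  expect_equal(haz(go, t), flexsurv::hgompertz(t, shape = -0.4, rate = 1.2),
               tolerance = 1e-10)
  wb <- family_params("weibull", shape = 1.7, rate = 0.8)
  expect_equal(surv(wb, t),
               stats::pweibull(t, 1.7, scale = 0.8^(-1 / 1.7),
                               lower.tail = FALSE),
               tolerance = 1e-12)
})
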