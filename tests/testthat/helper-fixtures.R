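# Shared fixtures and independent oracles.  Everything is generated in code;
# oracles (quadrature, finite differences, brute-force products) never reuse
# the code path they check.

# valid random parameter sets per family, away from singular corners
random_fp <- function(family, rng) {
  u <- function(a, b) stats::runif(1, a, b)
  withr_seedless <- switch(family,
    exponential = family_params("exponential", rate = u(0.2, 3)),
    weibull = family_params("weibull", shape = u(0.4, 3), rate = u(0.2, 3)),
    gompertz = family_params("gompertz", shape = u(-1.5, 1.5), rate = u(0.2, 3)),
    gamma = family_params("gamma", shape = u(0.4, 3), rate = u(0.2, 3)),
    loglogistic = family_params("loglogistic", shape = u(0.5, 4), rate = u(0.2, 3)),
    lognormal = family_params("lognormal", meanlog = u(-1, 1), sdlog = u(0.3, 1.5)),
    gengamma = family_params("gengamma", mu = u(-1, 1), sigma = u(0.4, 1.5),
                             Q = sample(c(-1, 1), 1) * u(0.1, 1.5))
  )
  withr_seedless
}

# quadrature oracle for the restricted mean, independent of rmst()'s closed
# forms: plain adaptive quadrature of the survival function
rmst_quad <- function(fp, horizon) {
  stats::integrate(function(u) surv(fp, u), 0, horizon,
                   abs.tol = 1e-10, rel.tol = 1e-10,
                   subdivisions = 1000L)$value
}

# central finite-difference hazard oracle: h(t) = -d/dt log S(t)
haz_fd <- function(fp, t, eps = 1e-6) {
  (log(surv(fp, t - eps)) - log(surv(fp, t + eps))) / (2 * eps)
}

# brute-force product-limit estimator and Greenwood variance
km_brute <- function(data) {
  tev <- sort(unique(data$time[data$event == 1]))
  surv <- numeric(length(tev)); vsum <- 0; s <- 1
  var <- numeric(length(tev))
  for (k in seq_along(tev)) {
    r <- sum(data$time >= tev[k])
    d <- sum(data$time == tev[k] & data$event == 1)
    s <- s * (1 - d / r)
    vsum <- vsum + d / (r * (r - d))
    surv[k] <- s
    var[k] <- s^2 * vsum
  }
  data.frame(time = tev, surv = surv, var = var)
}

toy_data <- function() survival_data(c(1, 2, 3, 4), c(1, 1, 0, 1))

# small censored dataset for fitting tests (cached per session)
flat_d400 <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- make_dataset(scenario_spec("flat", seed = 101))
    d
  }
})

increasing_d400 <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- make_dataset(scenario_spec("increasing", seed = 202))
    d
  }
})

# build a hazext_fit with a hand-set vcov (for degenerate-uncertainty tests)
fit_with_vcov <- function(fit, vc) {
  fit$vcov <- vc
  fit
}
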