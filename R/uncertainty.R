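# Propagation of parameter uncertainty Var(theta_hat) to hazard, survival and
# restricted-mean functionals by three routes:
#   * exact closed forms (exponential only),
#   * the delta method, Var(g) = grad(g)' Var(theta) grad(g), with numeric
#     gradients on the estimation scale,
#   * the multivariate-normal (MVN) Monte-Carlo method: draws
#     theta_b ~ N(theta_hat, Var(theta_hat)) on the estimation scale,
#     variance (1/B) sum_b [g(theta_b) - g(theta_hat)]^2 and percentile
#     95% limits.
# Sampling on the estimation scale guarantees every draw satisfies the
# family's parameter domain.

DEFAULT_SEED <- 20191125L

#' Evaluation time grid with an observed/extrapolated boundary
#'
#' @param times strictly increasing non-negative times (years).
#' @param observed_end boundary between the observed follow-up and the
#'   extrapolated period; must lie within the grid range.
#' @return Numeric vector of class `time_grid` with attribute
#'   `observed_end`.
#' @export
time_grid <- function(times, observed_end = max(times)) {
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times, strictly = TRUE))
    hazext_error("grid times must be non-negative and strictly increasing",
                 "hazext_usage_error")
  if (observed_end < min(times) || observed_end > max(times))
    hazext_error("`observed_end` must lie within the grid range",
                 "hazext_usage_error")
  structure(as.numeric(times), observed_end = observed_end,
            class = "time_grid")
}

as_time_grid <- function(grid) {
  if (inherits(grid, "time_grid")) grid else time_grid(grid)
}

new_curve_estimate <- function(time, point, se, lower, upper, quantity,
                               method, transform, observed_end) {
  structure(data.frame(time = time, point = point, se = se,
                       lower = lower, upper = upper),
            quantity = quantity, method = method, transform = transform,
            observed_end = observed_end,
            class = c("curve_estimate", "data.frame"))
}

#' @export
print.curve_estimate <- function(x, ...) {
  cat(sprintf("<curve_estimate> %s, method = %s, %d times (observed to %g)\n",
              attr(x, "quantity"), attr(x, "method"), nrow(x),
              attr(x, "observed_end")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Tidy export of curve estimates
#'
#' Flattens one or more [curve_estimate] objects into a tidy data frame with
#' columns `time, quantity, method, point, se, lower, upper, extrapolated`,
#' optionally writing it to CSV.
#'
#' @param curves a `curve_estimate` or list of them.
#' @param path optional CSV path.
#' @return The tidy data frame, invisibly when `path` is given.
#' @export
tidy_curves <- function(curves, path = NULL) {
  if (inherits(curves, "curve_estimate")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    df <- as.data.frame(cv)
    df$quantity <- attr(cv, "quantity")
    df$method <- attr(cv, "method")
    df$extrapolated <- df$time > attr(cv, "observed_end")
    df[, c("time", "quantity", "method", "point", "se", "lower", "upper",
           "extrapolated")]
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

quantity_fun <- function(quantity) {
  switch(quantity,
         hazard = haz,
         survival = surv,
         hazext_error("`quantity` must be 'hazard' or 'survival'",
                      "hazext_usage_error"))
}

check_fit <- function(fit) {
  if (!inherits(fit, "hazext_fit"))
    hazext_error("expected a `hazext_fit` object", "hazext_usage_error")
  fit
}

# ---- exact (exponential) ---------------------------------------------------

#' Exact uncertainty for the exponential model
#'
#' The exponential admits closed-form uncertainty: the variance of the
#' fitted hazard equals the variance of the rate, `rate^2 / N_events`,
#' constant over the whole time grid (the exponential's uncertainty does not
#' fan out during extrapolation); the mean survival is `1/rate` with
#' delta-method variance `1 / (rate^2 N_events)`.  Survival-function
#' standard errors follow by the delta method through
#' `S(t) = exp(-rate t)`.
#'
#' @param fit an exponential [hazext_fit].
#' @param grid a [time_grid()] (or numeric vector).
#' @param horizon horizon for the mean-survival estimate (default `Inf`,
#'   where the mean is `1/rate`).
#' @param level confidence level.
#' @return List with elements `hazard` and `survival` ([curve_estimate])
#'   and `mean` (a `mean_survival_estimate`).
#' @export
exact_exponential_uncertainty <- function(fit, grid, horizon = Inf,
                                          level = 0.95) {
  check_fit(fit)
  if (fit$family != "exponential")
    hazext_error("exact expressions are available for the exponential only",
                 "hazext_usage_error")
  grid <- as_time_grid(grid)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rate <- fit$fp$params$rate
  vr <- rate^2 / fit$n_events
  t <- as.numeric(grid)

  h_se <- rep(sqrt(vr), length(t))
  hz <- new_curve_estimate(t, rep(rate, length(t)), h_se,
                           pmax(rate - z * h_se, 0), rate + z * h_se,
                           "hazard", "exact", "identity",
                           attr(grid, "observed_end"))
  S <- exp(-rate * t)
  s_se <- t * S * sqrt(vr)              # |dS/drate| * se(rate)
  sv <- new_curve_estimate(t, S, s_se, pmax(S - z * s_se, 0),
                           pmin(S + z * s_se, 1),
                           "survival", "exact", "identity",
                           attr(grid, "observed_end"))
  mu <- rmst(fit$fp, horizon)
  mu_se <- if (is.infinite(horizon)) sqrt(1 / (rate^2 * fit$n_events))
           else sqrt(delta_variance(fit, function(fp) rmst(fp, horizon)))
  mean_est <- new_mean_survival(mu, mu_se, mu - z * mu_se, mu + z * mu_se,
                                horizon, "exact")
  list(hazard = hz, survival = sv, mean = mean_est)
}

# ---- delta method ----------------------------------------------------------

# numeric gradient of g(est-scale parameters), central differences
est_gradient <- function(fit, g_est, rel_step = 1e-6) {
  est <- fit$par_est
  p <- length(est)
  h <- rel_step * pmax(abs(est), 1)
  g0 <- g_est(est)
  k <- length(g0)
  G <- matrix(NA_real_, k, p)
  for (j in seq_len(p)) {
    ej <- replace(numeric(p), j, h[j])
    up <- g_est(est + ej); dn <- g_est(est - ej)
    if (any(!is.finite(up)) || any(!is.finite(dn)))
      hazext_error("gradient evaluation failed at the estimates",
                   "hazext_delta_error")
    G[, j] <- (up - dn) / (2 * h[j])
  }
  G
}

#' Delta-method variance of a functional of the fitted parameters
#'
#' Linearises `g` around the estimates on the estimation scale and returns
#' `grad(g)' Var(theta_hat) grad(g)`.  For the exponential hazard at any
#' time this reproduces the exact variance `rate^2 / N_events`.
#'
#' @param fit a [hazext_fit].
#' @param g a function of a [family_params()] object returning a scalar
#'   (e.g. `function(fp) haz(fp, 2)`).
#' @return Scalar variance of `g` at the estimates.
#' @examples
#' d <- survival_data(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' f <- fit_exponential_exact(d)
#' delta_variance(f, function(fp) haz(fp, 5))   # = 0.3^2 / 3
#' @export
delta_variance <- function(fit, g) {
  check_fit(fit)
  g_est <- function(est) g(from_estimation(fit$family, est))
  G <- est_gradient(fit, g_est)
  drop(G %*% fit$vcov %*% t(G))
}

#' Delta-method hazard or survival curve
#'
#' Pointwise delta-method standard errors for the fitted hazard or survival
#' function over a time grid, with normal-approximation 95% bands built on a
#' transformed scale (default `log` for the hazard so the band stays
#' positive, `logit` for survival so it stays in `[0, 1]`) and
#' back-transformed.
#'
#' @inheritParams exact_exponential_uncertainty
#' @param fit a [hazext_fit].
#' @param quantity `"hazard"` or `"survival"`.
#' @param transform banding transform: `"log"`, `"logit"` or `"identity"`.
#' @return A [curve_estimate]; `se` is on the natural scale.
#' @export
delta_curve <- function(fit, quantity = c("hazard", "survival"), grid,
                        transform = NULL, level = 0.95) {
  check_fit(fit)
  quantity <- match.arg(quantity)
  grid <- as_time_grid(grid)
  transform <- transform %||% if (quantity == "hazard") "log" else "logit"
  t <- as.numeric(grid)
  qf <- quantity_fun(quantity)
  g_est <- function(est) qf(from_estimation(fit$family, est), t)
  G <- est_gradient(fit, g_est)
  v <- rowSums((G %*% fit$vcov) * G)
  point <- qf(fit$fp, t)
  cv <- new_curve_estimate(t, point, sqrt(pmax(v, 0)), NA_real_, NA_real_,
                           quantity, "delta", transform,
                           attr(grid, "observed_end"))
  band_transform(cv, transform, level = level)
}

# ---- multivariate-normal method -------------------------------------------

#' Multivariate-normal parameter draws
#'
#' Draws `B` parameter vectors from `N(theta_hat, Var(theta_hat))` on the
#' estimation scale.  Back-transformation guarantees every draw satisfies
#' the family's natural-scale domain.  With a fixed `seed` the draws are
#' reproducible, so hazard, survival and mean-survival summaries built from
#' the same `fit`, `B` and `seed` are mutually coherent draw by draw.
#'
#' @param fit a [hazext_fit].
#' @param B number of draws (>= 100 recommended).
#' @param seed integer seed (default `20191125`).
#' @return A `B x p` matrix of estimation-scale draws.
#' @export
mvn_parameter_draws <- function(fit, B = 1000, seed = DEFAULT_SEED) {
  check_fit(fit)
  if (B < 2) hazext_error("`B` must be at least 2", "hazext_usage_error")
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    hazext_error(paste0(
      "Var(theta_hat) is not positive semi-definite; repair it (e.g. ",
      "nearest-PSD projection) before sampling"), "hazext_psd_error")
  draws <- with_local_seed(seed,
    MASS::mvrnorm(B, mu = fit$par_est, Sigma = fit$vcov, tol = 1e-6))
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  colnames(draws) <- names(fit$par_est)
  draws
}

#' Multivariate-normal uncertainty for hazard or survival curves
#'
#' Monte-Carlo propagation: `B` parameter draws from
#' `N(theta_hat, Var(theta_hat))` are pushed through the hazard or survival
#' function over the grid.  The reported standard error is
#' `sqrt((1/B) sum_b [g(theta_b) - g(theta_hat)]^2)` and the 95% limits are
#' the 2.5th/97.5th percentiles of the draws (percentile bands are invariant
#' to monotone transforms, so hazard bands are non-negative and survival
#' bands stay within `[0, 1]` automatically).
#'
#' @inheritParams delta_curve
#' @inheritParams mvn_parameter_draws
#' @return A [curve_estimate] with `method = "mvn"`.
#' @export
mvn_curve <- function(fit, quantity = c("hazard", "survival"), grid,
                      B = 1000, seed = DEFAULT_SEED, level = 0.95) {
  check_fit(fit)
  quantity <- match.arg(quantity)
  grid <- as_time_grid(grid)
  t <- as.numeric(grid)
  qf <- quantity_fun(quantity)
  draws <- mvn_parameter_draws(fit, B, seed)
  M <- apply(draws, 1, function(est) qf(from_estimation(fit$family, est), t))
  M <- matrix(M, nrow = length(t))       # times x B
  point <- qf(fit$fp, t)
  se <- sqrt(rowMeans((M - point)^2))
  alpha <- (1 - level) / 2
  qs <- apply(M, 1, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  new_curve_estimate(t, point, se, qs[1, ], qs[2, ], quantity, "mvn",
                     "percentile", attr(grid, "observed_end"))
}

# ---- mean survival ---------------------------------------------------------

new_mean_survival <- function(point, se, lower, upper, horizon, method,
                              B = NA_integer_, seed = NA_integer_) {
  structure(list(point = point, se = se, lower = lower, upper = upper,
                 horizon = horizon, method = method, B = B, seed = seed),
            class = "mean_survival_estimate")
}

#' @export
print.mean_survival_estimate <- function(x, ...) {
  cat(sprintf(
    "<mean_survival_estimate> %.4f years (se %.4f, 95%% CI %.4f-%.4f), horizon %s, method %s\n",
    x$point, x$se, x$lower, x$upper,
    if (is.infinite(x$horizon)) "Inf" else format(x$horizon), x$method))
  invisible(x)
}

#' Mean survival with uncertainty
#'
#' Point estimate `integral of S(t), 0..horizon` at the fitted parameters,
#' with standard error and 95% interval by the requested route: `"exact"`
#' (exponential, infinite horizon), `"delta"` or `"mvn"`.  MVN intervals are
#' percentiles of the restricted-mean draws; with the same `seed` the draws
#' are the ones used by [mvn_curve()], so curve and mean summaries are
#' coherent.
#'
#' An infinite horizon combined with a fit whose survival is improper or
#' heavy-tailed (e.g. Gompertz with negative shape) signals a
#' diverging-mean error; use a finite horizon (the package default for
#' lifetime summaries is the 10-year decision horizon).
#'
#' @inheritParams mvn_curve
#' @param horizon years (default 10, the decision horizon; may be `Inf`).
#' @param method `"mvn"`, `"delta"` or `"exact"`.
#' @return A `mean_survival_estimate`.
#' @export
mean_survival <- function(fit, horizon = 10,
                          method = c("mvn", "delta", "exact"),
                          B = 1000, seed = DEFAULT_SEED, level = 0.95) {
  check_fit(fit)
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - level) / 2)
  point <- rmst(fit$fp, horizon)
  if (method == "exact") {
    if (fit$family != "exponential" || !is.infinite(horizon))
      hazext_error(
        "method 'exact' applies to the exponential with horizon = Inf",
        "hazext_usage_error")
    rate <- fit$fp$params$rate
    se <- sqrt(1 / (rate^2 * fit$n_events))
    return(new_mean_survival(point, se, point - z * se, point + z * se,
                             horizon, "exact"))
  }
  if (method == "delta") {
    v <- delta_variance(fit, function(fp) rmst(fp, horizon))
    se <- sqrt(max(v, 0))
    return(new_mean_survival(point, se, max(point - z * se, 0),
                             point + z * se, horizon, "delta"))
  }
  draws <- mvn_parameter_draws(fit, B, seed)
  vals <- apply(draws, 1, function(est)
    rmst(from_estimation(fit$family, est), horizon))
  se <- sqrt(mean((vals - point)^2))
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  new_mean_survival(point, se, min(q[1], point), max(q[2], point), horizon,
                    "mvn", B = B, seed = seed)
}

# ---- band transforms -------------------------------------------------------

#' Rebuild confidence bands on a transformed scale
#'
#' Normal-approximation bands (methods `exact` and `delta`) are recomputed
#' on the requested scale — `trans(point) +/- z * se_trans` with
#' `se_trans = se * |trans'(point)|` — and back-transformed, keeping hazard
#' bands non-negative (`log`) or survival bands inside `[0, 1]` (`logit`).
#' Percentile bands (method `mvn`) commute with monotone transforms, so
#' they are returned unchanged.
#'
#' @param curve a [curve_estimate].
#' @param transform `"log"`, `"logit"` or `"identity"`.
#' @param level confidence level.
#' @return A [curve_estimate] with updated bands.
#' @export
band_transform <- function(curve, transform = c("log", "logit", "identity"),
                           level = 0.95) {
  if (!inherits(curve, "curve_estimate"))
    hazext_error("expected a `curve_estimate`", "hazext_usage_error")
  transform <- match.arg(transform)
  if (attr(curve, "method") == "mvn") {
    attr(curve, "transform") <- "percentile"
    return(curve)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- curve$point; se <- curve$se
  if (transform == "log" && any(p <= 0))
    hazext_error(sprintf("log transform needs positive values; offending times: %s",
                         paste(utils::head(curve$time[p <= 0], 5), collapse = ", ")),
                 "hazext_domain_error")
  if (transform == "logit" && any(p <= 0 | p >= 1))
    hazext_error(sprintf("logit transform needs values in (0,1); offending times: %s",
                         paste(utils::head(curve$time[p <= 0 | p >= 1], 5),
                               collapse = ", ")),
                 "hazext_domain_error")
  band <- switch(transform,
    identity = list(lo = p - z * se, hi = p + z * se),
    log = {
      se_t <- se / p
      list(lo = p * exp(-z * se_t), hi = p * exp(z * se_t))
    },
    logit = {
      se_t <- se / (p * (1 - p))
      lg <- stats::qlogis(p)
      list(lo = stats::plogis(lg - z * se_t), hi = stats::plogis(lg + z * se_t))
    })
  curve$lower <- pmin(band$lo, p)
  curve$upper <- pmax(band$hi, p)
  attr(curve, "transform") <- transform
  curve
}
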