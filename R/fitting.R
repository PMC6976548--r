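# Maximum-likelihood estimation of the seven families from right-censored
# data.  The log-likelihood is the standard censored-data form
#   l(theta) = sum_i [ delta_i * log f(t_i) + (1 - delta_i) * log S(t_i) ]
# maximised on the unconstrained estimation scale (log for positive
# parameters).  Var(theta_hat) is the inverse of the negative Hessian of the
# log-likelihood at the optimum, obtained by central finite differences.

#' Fitted parametric survival model
#'
#' Objects of class `hazext_fit` are returned by [fit_parametric()] and
#' [fit_exponential_exact()].  Fields: `family`, `fp` (natural-scale
#' [family_params()]), `par_est` (estimation-scale estimates), `vcov`
#' (estimation-scale variance-covariance), `loglik`, `n`, `n_events`,
#' `converged`.
#'
#' @param x,object a `hazext_fit`.
#' @param ... unused.
#' @name hazext_fit
NULL

new_fit <- function(family, fp, par_est, vcov, loglik, n, n_events,
                    converged, method) {
  structure(list(family = family, fp = fp, par_est = par_est, vcov = vcov,
                 loglik = loglik, n = n, n_events = n_events,
                 converged = converged, method = method),
            class = "hazext_fit")
}

#' @rdname hazext_fit
#' @export
print.hazext_fit <- function(x, ...) {
  cat(sprintf("<hazext_fit> %s (%s), n = %d, events = %d, logLik = %.3f%s\n",
              x$family, x$method, x$n, x$n_events, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = unlist(x$fp$params),
                    est.scale = unname(x$par_est), se.est.scale = unname(se))
  rownames(tab) <- names(x$fp$params)
  print(round(tab, 5))
  invisible(x)
}

#' @rdname hazext_fit
#' @export
coef.hazext_fit <- function(object, ...) unlist(object$fp$params)

#' @rdname hazext_fit
#' @export
vcov.hazext_fit <- function(object, ...) object$vcov

#' @rdname hazext_fit
#' @export
logLik.hazext_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par_est), class = "logLik")
}

# censored-data log-likelihood on the estimation scale
neg_loglik_fn <- function(data, family) {
  t_ev <- data$time[data$event == 1]
  t_cn <- data$time[data$event == 0]
  function(est) {
    fp <- tryCatch(from_estimation(family, est), error = function(e) NULL)
    if (is.null(fp)) return(1e10)
    ll <- 0
    if (length(t_ev)) ll <- ll + sum(logdens(fp, t_ev))
    if (length(t_cn)) ll <- ll + sum(log_surv(fp, t_cn))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

#' Starting values for maximum-likelihood fitting
#'
#' Moment/quantile-based starting values on the natural scale, anchored on
#' the closed-form exponential rate `N_events / sum(t_i)`.  The generalised
#' gamma starts from the fitted Weibull embedding (`Q = 1`,
#' `sigma = 1/shape`, `mu = -log(rate)/shape`), which guarantees its
#' maximised likelihood is at least the Weibull's.  Degenerate data (all
#' event times identical) fall back to documented constants with a warning.
#'
#' @param data a [survival_data()].
#' @param family family name.
#' @return A [family_params()] object usable as an optimiser start.
#' @export
start_values <- function(data, family) {
  data <- check_data(data)
  if (n_events(data) < 1)
    hazext_error("no events in data", "hazext_no_events_error")
  rate0 <- n_events(data) / sum(data$time)
  lt <- log(data$time[data$event == 1])
  sd_lt <- stats::sd(lt)
  if (!is.finite(sd_lt) || sd_lt < 1e-8) {
    warning("degenerate event times; using fallback spread for start values")
    sd_lt <- 0.5
  }
  switch(family,
    exponential = family_params("exponential", rate = rate0),
    weibull = family_params("weibull", shape = 1, rate = rate0),
    gamma = family_params("gamma", shape = 1, rate = rate0),
    gompertz = family_params("gompertz", shape = 0, rate = rate0),
    lognormal = family_params("lognormal", meanlog = mean(lt), sdlog = sd_lt),
    loglogistic = {
      # log T is logistic with scale 1/shape: sd = pi/(shape * sqrt(3))
      b0 <- max(pi / (sqrt(3) * sd_lt), 0.1)
      family_params("loglogistic", shape = b0, rate = exp(-mean(lt)))
    },
    gengamma = {
      wb <- fit_parametric(data, "weibull")$fp$params
      family_params("gengamma", mu = -log(wb$rate) / wb$shape,
                    sigma = 1 / wb$shape, Q = 1)
    },
    hazext_error(sprintf("unknown family '%s'", family),
                 "hazext_domain_error")
  )
}

# central-difference Hessian, relative step 1e-5
fd_hessian <- function(f, x, rel_step = 1e-5) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    for (j in seq_len(p)) {
      if (j >= i) next
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

#' Fit a parametric survival family by maximum likelihood
#'
#' Maximises the right-censored log-likelihood on the unconstrained
#' estimation scale (log for strictly positive parameters, identity for the
#' Gompertz shape, log-normal `meanlog` and generalised-gamma `mu` and `Q`)
#' with a quasi-Newton optimiser restarted from three jittered starting
#' points.  The variance-covariance matrix of the estimates is the inverse
#' of the negative Hessian of the log-likelihood at the optimum (central
#' finite differences, relative step `1e-5`).  Non-convergence is flagged on
#' the returned object and warned about, not hidden.
#'
#' @param data a [survival_data()] (or data.frame with `time`/`event`).
#' @param family family name, see [family_params()].
#' @param start optional [family_params()] starting values.
#' @return A [hazext_fit] object.
#' @examples
#' d <- make_dataset(scenario_spec("flat", seed = 1))
#' fit_parametric(d, "weibull")
#' @export
fit_parametric <- function(data, family, start = NULL) {
  data <- check_data(data)
  family <- match.arg(family, SURVIVAL_FAMILIES)
  npar <- length(fam_def(family)$pars)
  if (n_events(data) < npar)
    hazext_error(sprintf("need at least %d events to fit a %s model",
                         npar, family), "hazext_no_events_error")
  fp0 <- start %||% start_values(data, family)
  est0 <- to_estimation(fp0)
  nll <- neg_loglik_fn(data, family)

  starts <- list(est0)
  jit <- with_local_seed(20191125L, lapply(1:2, function(i)
    est0 + stats::rnorm(length(est0), sd = 0.3)))
  starts <- c(starts, jit)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    hazext_error(sprintf("optimisation failed for family '%s'", family),
                 "hazext_fit_error")
  converged <- best$convergence == 0
  if (!converged)
    warning(sprintf("optimiser did not converge for family '%s'", family))
  est <- best$par
  names(est) <- estimation_par_names(family)

  H <- fd_hessian(nll, est)       # Hessian of the NEGATIVE log-likelihood
  vc <- tryCatch(solve(H), error = function(e)
    hazext_error(sprintf("singular Hessian for family '%s'", family),
                 "hazext_fit_error"))
  vc <- (vc + t(vc)) / 2
  if (any(diag(vc) < 0))
    hazext_error(sprintf("Hessian not positive definite for family '%s'",
                         family), "hazext_fit_error")
  dimnames(vc) <- list(names(est), names(est))
  new_fit(family, from_estimation(family, est), est, vc,
          loglik = -best$value, n = nrow(data), n_events = n_events(data),
          converged = converged, method = "mle")
}

#' Closed-form exponential fit
#'
#' The exponential model has exact maximum-likelihood solutions under right
#' censoring: `rate_hat = N_events / sum(t_i)` with natural-scale variance
#' `rate_hat^2 / N_events`.  On the log estimation scale this corresponds to
#' `Var(log rate_hat) = 1 / N_events`.
#'
#' @param data a [survival_data()].
#' @return A [hazext_fit] with `method = "closed_form"`.
#' @examples
#' d <- survival_data(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' f <- fit_exponential_exact(d)   # rate 0.3, Var 0.03
#' @export
fit_exponential_exact <- function(data) {
  data <- check_data(data)
  Ne <- n_events(data)
  if (Ne == 0)
    hazext_error("no events: the exponential rate is not estimable",
                 "hazext_no_events_error")
  rate <- Ne / sum(data$time)
  fp <- family_params("exponential", rate = rate)
  vc <- matrix(1 / Ne, 1, 1,
               dimnames = list("log(rate)", "log(rate)"))
  ll <- -neg_loglik_fn(data, "exponential")(log(rate))
  new_fit("exponential", fp, c("log(rate)" = log(rate)), vc, ll,
          n = nrow(data), n_events = Ne, converged = TRUE,
          method = "closed_form")
}

#' Natural-scale variance of the exponential rate (and hazard)
#'
#' For a closed-form exponential fit, `Var(rate_hat) = rate_hat^2 /
#' N_events`, which is also the time-constant variance of the fitted hazard.
#'
#' @param fit an exponential [hazext_fit].
#' @return Scalar variance.
#' @export
exp_rate_variance <- function(fit) {
  if (fit$family != "exponential")
    hazext_error("exact variance formulas apply to the exponential only",
                 "hazext_usage_error")
  fit$fp$params$rate^2 / fit$n_events
}
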