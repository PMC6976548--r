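# Seven parametric survival families in the proportional-hazards style
# parameterisation used throughout the package.  All families are defined on
# the natural scale through their cumulative hazard H(t); survival, hazard and
# density follow from S(t) = exp(-H(t)) and f(t) = h(t) S(t).
#
# Natural-scale parameterisations (t >= 0):
#   exponential  rate > 0                      H(t) = rate * t
#   weibull      shape > 0, rate > 0           H(t) = rate * t^shape
#   gompertz     shape in R, rate > 0          h(t) = rate * exp(shape * t)
#   gamma        shape > 0, rate > 0           standard shape--rate gamma
#   loglogistic  shape > 0, rate > 0           S(t) = 1 / (1 + (rate*t)^shape)
#   lognormal    meanlog in R, sdlog > 0       standard log-normal
#   gengamma     mu in R, sigma > 0, Q in R    Prentice generalised gamma
#
# Conversion to other software conventions:
#   * R's dweibull(shape, scale): scale = rate^(-1/shape)
#     (identical to flexsurv::dweibullPH).
#   * flexsurv::dllogis(shape, scale): scale = 1/rate.
#   * flexsurv::dgengamma(mu, sigma, Q): identical names and meaning; Q = 0 is
#     the log-normal, Q = 1 a Weibull with shape 1/sigma and rate
#     exp(-mu/sigma).
#   * gompertz and gamma match flexsurv::dgompertz / stats::dgamma directly.

SURVIVAL_FAMILIES <- c("exponential", "weibull", "gompertz", "gamma",
                       "loglogistic", "lognormal", "gengamma")

# ---- family registry -------------------------------------------------------
# Each entry: parameter names, domain check, estimation-scale transform per
# parameter ("log" for strictly positive, "identity" for unconstrained),
# cumulative hazard / log-survival / log-density / hazard, sampler, mean,
# finite-mean predicate, and the t -> 0+ hazard limit.

.fam <- new.env(parent = emptyenv())

.fam$exponential <- list(
  pars = "rate",
  transform = c(rate = "log"),
  check = function(p) p$rate > 0,
  H = function(p, t) p$rate * t,
  h = function(p, t) rep_len(p$rate, length(t)),
  logf = function(p, t) log(p$rate) - p$rate * t,
  rng = function(p, n) stats::rexp(n, rate = p$rate),
  mean = function(p) 1 / p$rate,
  finite_mean = function(p) TRUE,
  h0 = function(p) p$rate,
  rmst = function(p, h) -expm1(-p$rate * h) / p$rate
)

.fam$weibull <- list(
  pars = c("shape", "rate"),
  transform = c(shape = "log", rate = "log"),
  check = function(p) p$shape > 0 && p$rate > 0,
  H = function(p, t) p$rate * t^p$shape,
  h = function(p, t) p$rate * p$shape * t^(p$shape - 1),
  logf = function(p, t)
    log(p$rate) + log(p$shape) + (p$shape - 1) * log(t) - p$rate * t^p$shape,
  rng = function(p, n)
    stats::rweibull(n, shape = p$shape, scale = p$rate^(-1 / p$shape)),
  mean = function(p) p$rate^(-1 / p$shape) * gamma(1 + 1 / p$shape),
  finite_mean = function(p) TRUE,
  h0 = function(p) if (p$shape > 1) 0 else if (p$shape == 1) p$rate else Inf,
  # restricted mean via the partial expectation of a gamma variate:
  # with u = rate * h^shape, E[T 1(T<=h)] = rate^(-1/shape) *
  #   Gamma(1 + 1/shape) * P(1 + 1/shape, u).
  rmst = function(p, h) {
    u <- p$rate * h^p$shape
    h * exp(-u) + p$rate^(-1 / p$shape) * gamma(1 + 1 / p$shape) *
      stats::pgamma(u, shape = 1 + 1 / p$shape)
  }
)

.fam$gompertz <- list(
  pars = c("shape", "rate"),
  transform = c(shape = "identity", rate = "log"),
  check = function(p) p$rate > 0 && is.finite(p$shape),
  H = function(p, t)
    if (p$shape == 0) p$rate * t else p$rate * expm1(p$shape * t) / p$shape,
  h = function(p, t) p$rate * exp(p$shape * t),
  logf = function(p, t) {
    H <- if (p$shape == 0) p$rate * t else p$rate * expm1(p$shape * t) / p$shape
    log(p$rate) + p$shape * t - H
  },
  rng = function(p, n) {
    if (p$shape == 0) return(stats::rexp(n, rate = p$rate))
    # inverse cumulative hazard; shape < 0 gives a cured fraction (Inf times)
    u <- stats::runif(n)
    arg <- 1 - p$shape * log(u) / p$rate
    out <- rep(Inf, n)
    ok <- arg > 0
    out[ok] <- log(arg[ok]) / p$shape
    out
  },
  mean = function(p) {
    if (p$shape < 0) return(Inf)
    .quad_mean(function(t) exp(-.fam$gompertz$H(p, t)))
  },
  finite_mean = function(p) p$shape >= 0,
  h0 = function(p) p$rate,
  rmst = NULL   # no elementary closed form; adaptive quadrature is used
)

.fam$gamma <- list(
  pars = c("shape", "rate"),
  transform = c(shape = "log", rate = "log"),
  check = function(p) p$shape > 0 && p$rate > 0,
  logS = function(p, t)
    stats::pgamma(t, shape = p$shape, rate = p$rate,
                  lower.tail = FALSE, log.p = TRUE),
  logf = function(p, t) stats::dgamma(t, shape = p$shape, rate = p$rate,
                                      log = TRUE),
  rng = function(p, n) stats::rgamma(n, shape = p$shape, rate = p$rate),
  mean = function(p) p$shape / p$rate,
  finite_mean = function(p) TRUE,
  h0 = function(p) if (p$shape > 1) 0 else if (p$shape == 1) p$rate else Inf,
  rmst = function(p, h) {
    S <- stats::pgamma(h, p$shape, rate = p$rate, lower.tail = FALSE)
    h * S + (p$shape / p$rate) * stats::pgamma(h, p$shape + 1, rate = p$rate)
  }
)

.fam$loglogistic <- list(
  pars = c("shape", "rate"),
  transform = c(shape = "log", rate = "log"),
  check = function(p) p$shape > 0 && p$rate > 0,
  # stable forms in lx = shape * log(rate * t):
  #   H = log(1 + e^lx),  h = (shape/t) * logistic(lx)
  H = function(p, t) log1pexp(p$shape * (log(p$rate) + log(t))),
  h = function(p, t) {
    lx <- p$shape * (log(p$rate) + log(t))
    (p$shape / t) * stats::plogis(lx)
  },
  logf = function(p, t) {
    lx <- p$shape * (log(p$rate) + log(t))
    log(p$shape) - log(t) + lx - 2 * log1pexp(lx)
  },
  rng = function(p, n) {
    u <- stats::runif(n)
    (u / (1 - u))^(1 / p$shape) / p$rate
  },
  mean = function(p) {
    if (p$shape <= 1) return(Inf)
    b <- pi / p$shape
    b / (p$rate * sin(b))
  },
  finite_mean = function(p) p$shape > 1,
  h0 = function(p) if (p$shape > 1) 0 else if (p$shape == 1) p$rate else Inf,
  rmst = function(p, h) {
    if (p$shape <= 1) return(NULL)  # fall back to quadrature
    x <- (p$rate * h)^p$shape
    Fh <- x / (1 + x)
    a <- 1 + 1 / p$shape; b <- 1 - 1 / p$shape
    h / (1 + x) + beta(a, b) * stats::pbeta(Fh, a, b) / p$rate
  }
)

.fam$lognormal <- list(
  pars = c("meanlog", "sdlog"),
  transform = c(meanlog = "identity", sdlog = "log"),
  check = function(p) is.finite(p$meanlog) && p$sdlog > 0,
  logS = function(p, t)
    stats::plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE, log.p = TRUE),
  logf = function(p, t) stats::dlnorm(t, p$meanlog, p$sdlog, log = TRUE),
  rng = function(p, n) stats::rlnorm(n, p$meanlog, p$sdlog),
  mean = function(p) exp(p$meanlog + p$sdlog^2 / 2),
  finite_mean = function(p) TRUE,
  h0 = function(p) 0,
  rmst = function(p, h) {
    S <- stats::plnorm(h, p$meanlog, p$sdlog, lower.tail = FALSE)
    h * S + exp(p$meanlog + p$sdlog^2 / 2) *
      stats::pnorm((log(h) - p$meanlog - p$sdlog^2) / p$sdlog)
  }
)

# Prentice generalised gamma.  With w = (log t - mu)/sigma and a = Q^-2:
#   S(t) = 1 - P(a * exp(Q w); a)   (Q > 0)
#        = P(a * exp(Q w); a)       (Q < 0)
#   log f(t) = log|Q| - log(sigma t) - lgamma(a)
#              + a [log a + Q w - exp(Q w)]
# Q = 0 is exactly the log-normal(mu, sigma).
.fam$gengamma <- list(
  pars = c("mu", "sigma", "Q"),
  transform = c(mu = "identity", sigma = "log", Q = "identity"),
  check = function(p) is.finite(p$mu) && p$sigma > 0 && is.finite(p$Q),
  logS = function(p, t) {
    if (p$Q == 0)
      return(stats::plnorm(t, p$mu, p$sigma, lower.tail = FALSE, log.p = TRUE))
    a <- p$Q^-2
    w <- (log(t) - p$mu) / p$sigma
    u <- a * exp(p$Q * w)
    stats::pgamma(u, shape = a, lower.tail = p$Q < 0, log.p = TRUE)
  },
  logf = function(p, t) {
    if (p$Q == 0) return(stats::dlnorm(t, p$mu, p$sigma, log = TRUE))
    a <- p$Q^-2
    w <- (log(t) - p$mu) / p$sigma
    qw <- p$Q * w
    log(abs(p$Q)) - log(p$sigma) - log(t) - lgamma(a) +
      a * log(a) - a + a * (qw - expm1(qw))
  },
  rng = function(p, n) {
    if (p$Q == 0) return(stats::rlnorm(n, p$mu, p$sigma))
    g <- stats::rgamma(n, shape = p$Q^-2)
    exp(p$mu + p$sigma * log(p$Q^2 * g) / p$Q)
  },
  mean = function(p) {
    if (p$Q == 0) return(exp(p$mu + p$sigma^2 / 2))
    a <- p$Q^-2
    s <- p$sigma / p$Q
    if (a + s <= 0) return(Inf)
    exp(p$mu + s * log(p$Q^2) + lgamma(a + s) - lgamma(a))
  },
  finite_mean = function(p) p$Q >= 0 || p$sigma * abs(p$Q) < 1,
  h0 = function(p) {
    if (p$Q <= 0) return(0)
    k <- 1 / (p$Q * p$sigma)        # local power of t in the density near 0
    if (k > 1) 0 else if (k == 1) NA_real_ else Inf
  },
  rmst = function(p, h) {
    if (p$Q == 0) return(.fam$lognormal$rmst(list(meanlog = p$mu,
                                                  sdlog = p$sigma), h))
    a <- p$Q^-2
    s <- p$sigma / p$Q
    if (a + s <= 0) return(NULL)
    w <- (log(h) - p$mu) / p$sigma
    u <- a * exp(p$Q * w)
    S <- stats::pgamma(u, shape = a, lower.tail = p$Q < 0)
    m <- exp(p$mu + s * log(p$Q^2) + lgamma(a + s) - lgamma(a))
    part <- stats::pgamma(u, shape = a + s, lower.tail = p$Q > 0)
    h * S + m * part
  }
)

.quad_mean <- function(Sfun) {
  stats::integrate(Sfun, 0, Inf, abs.tol = 1e-8, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

fam_def <- function(family) {
  if (!family %in% SURVIVAL_FAMILIES)
    hazext_error(sprintf("unknown family '%s'; must be one of: %s", family,
                         paste(SURVIVAL_FAMILIES, collapse = ", ")),
                 "hazext_domain_error")
  get(family, envir = .fam)
}

# ---- FamilyParams ----------------------------------------------------------

#' Parametric survival family with natural-scale parameters
#'
#' Constructs a validated parameter object for one of the seven survival
#' families used throughout the package: `exponential`, `weibull`,
#' `gompertz`, `gamma`, `loglogistic`, `lognormal` and `gengamma`.
#'
#' The Weibull and log-logistic use a proportional-hazards style `rate`
#' parameter: Weibull `H(t) = rate * t^shape` (so `rate = scale^-shape`
#' relative to [stats::dweibull()]), log-logistic
#' `S(t) = 1/(1 + (rate*t)^shape)` (so `rate = 1/scale` relative to
#' `flexsurv::dllogis`).  The generalised gamma uses the Prentice
#' `(mu, sigma, Q)` parameterisation (as in `flexsurv::dgengamma`); `Q = 0`
#' is the log-normal and `Q = 1` a Weibull with shape `1/sigma` and rate
#' `exp(-mu/sigma)`.  A Gompertz with negative `shape` is an improper
#' distribution: a fraction `exp(-rate/|shape|)` of subjects never
#' experiences the event.
#'
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"gamma"`, `"loglogistic"`, `"lognormal"`, `"gengamma"`.
#' @param ... named natural-scale parameters (see Details); alternatively a
#'   single named numeric vector.
#' @return An object of class `family_params`.
#' @examples
#' fp <- family_params("weibull", shape = 2, rate = 1.3)
#' surv(fp, c(0.5, 1, 2))
#' haz(fp, 1)
#' rmst(fp, horizon = 10)
#' @export
family_params <- function(family, ...) {
  family <- match.arg(family, SURVIVAL_FAMILIES)
  def <- fam_def(family)
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.numeric(dots[[1]]) &&
      !is.null(names(dots[[1]])))
    dots <- as.list(dots[[1]])
  if (!setequal(names(dots), def$pars) || anyDuplicated(names(dots)))
    hazext_error(sprintf("family '%s' takes parameters: %s", family,
                         paste(def$pars, collapse = ", ")),
                 "hazext_domain_error")
  p <- lapply(dots[def$pars], function(x) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      hazext_error("parameters must be finite scalars", "hazext_domain_error")
    as.numeric(x)
  })
  if (!def$check(p))
    hazext_error(sprintf("invalid parameters for family '%s'", family),
                 "hazext_domain_error")
  structure(list(family = family, params = p), class = "family_params")
}

#' @export
print.family_params <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$family,
              paste(sprintf("%s = %g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

check_fp <- function(fp) {
  if (!inherits(fp, "family_params"))
    hazext_error("expected a `family_params` object", "hazext_usage_error")
  fp
}

check_times <- function(t, positive = FALSE) {
  if (!is.numeric(t) || any(!is.finite(t)) ||
      any(t < 0) || (positive && any(t <= 0)))
    hazext_error(sprintf("times must be finite and %s",
                         if (positive) "> 0" else ">= 0"),
                 "hazext_domain_error")
  t
}

# ---- functionals -----------------------------------------------------------

log_surv <- function(fp, t) {
  def <- fam_def(fp$family)
  if (!is.null(def[["logS"]])) def[["logS"]](fp$params, t) else -def[["H"]](fp$params, t)
}

#' Survival, hazard, cumulative hazard and log-density
#'
#' Evaluate the survival function `S(t)`, hazard `h(t)` (events per year),
#' cumulative hazard `H(t) = -log S(t)` and log-density
#' `log f(t) = log h(t) + log S(t)` of a parametric family.
#'
#' `haz()` at `t = 0` returns the analytic limit where it is finite (for
#' example 0 for the log-normal, `rate` for the exponential) and signals a
#' domain error where the hazard diverges at the origin (Weibull or gamma
#' with `shape < 1`, log-logistic with `shape < 1`).
#'
#' @param fp a [family_params()] object.
#' @param t vector of non-negative times in years (strictly positive for
#'   `logdens`).
#' @return Numeric vector of the same length as `t`.
#' @seealso [rmst()], [rtimes()]
#' @export
surv <- function(fp, t) {
  check_fp(fp); check_times(t)
  exp(log_surv(fp, pmax(t, 0)))
}

#' @rdname surv
#' @export
cumhaz <- function(fp, t) {
  check_fp(fp); check_times(t)
  def <- fam_def(fp$family)
  if (!is.null(def[["H"]])) def[["H"]](fp$params, t) else -def[["logS"]](fp$params, t)
}

#' @rdname surv
#' @export
haz <- function(fp, t) {
  check_fp(fp); check_times(t)
  def <- fam_def(fp$family)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    out[pos] <- if (!is.null(def[["h"]])) def[["h"]](fp$params, tp)
                else exp(def$logf(fp$params, tp) - log_surv(fp, tp))
  }
  if (any(!pos)) {
    lim <- def$h0(fp$params)
    if (!is.finite(lim))
      hazext_error(sprintf(
        "hazard of family '%s' diverges at t = 0 for these parameters; use t > 0",
        fp$family), "hazext_domain_error")
    out[!pos] <- lim
  }
  out
}

#' @rdname surv
#' @export
logdens <- function(fp, t) {
  check_fp(fp); check_times(t, positive = TRUE)
  fam_def(fp$family)$logf(fp$params, t)
}

#' Random survival times
#'
#' Draws `n` event times from a parametric family.  Improper distributions
#' (Gompertz with negative shape) return `Inf` for the never-event fraction.
#'
#' @param fp a [family_params()] object.
#' @param n number of draws.
#' @param seed optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return Numeric vector of `n` positive times (possibly `Inf`).
#' @export
rtimes <- function(fp, n, seed = NULL) {
  check_fp(fp)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    hazext_error("`n` must be a positive count", "hazext_usage_error")
  with_local_seed(seed, fam_def(fp$family)$rng(fp$params, as.integer(n)))
}

#' Mean and restricted mean survival time
#'
#' `rmst()` computes the restricted mean survival time
#' `integral of S(t) from 0 to horizon`; `horizon = Inf` gives the
#' (unrestricted) mean where it exists.  Closed forms are used for the
#' exponential, Weibull, gamma, log-normal, log-logistic (`shape > 1`) and
#' generalised gamma; the Gompertz (and log-logistic with `shape <= 1` at
#' finite horizons) falls back to adaptive quadrature with absolute
#' tolerance `1e-8`.  Infinite horizons are integrated after the change of
#' variables performed by [stats::integrate()].
#'
#' For an improper or heavy-tailed fit (Gompertz `shape < 0`, log-logistic
#' `shape <= 1`, generalised gamma with `sigma * |Q| >= 1` and `Q < 0`) the
#' unrestricted mean diverges and `horizon = Inf` signals an error of class
#' `hazext_diverging_mean_error`; use a finite horizon instead.
#'
#' @inheritParams surv
#' @param horizon positive horizon in years, possibly `Inf`.
#' @return Mean survival time in years, in `(0, horizon]`.
#' @export
rmst <- function(fp, horizon) {
  check_fp(fp)
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) ||
      horizon <= 0)
    hazext_error("`horizon` must be a positive number (possibly Inf)",
                 "hazext_usage_error")
  def <- fam_def(fp$family)
  if (is.infinite(horizon)) {
    if (!def$finite_mean(fp$params))
      hazext_error(paste0(
        "mean survival diverges for this ", fp$family,
        " fit (improper or heavy-tailed survival); request a finite horizon"),
        "hazext_diverging_mean_error")
    return(def$mean(fp$params))
  }
  if (!is.null(def[["rmst"]])) {
    out <- def[["rmst"]](fp$params, horizon)
    if (!is.null(out)) return(out)
  }
  stats::integrate(function(u) exp(log_surv(fp, u)), 0, horizon,
                   abs.tol = 1e-8, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

# ---- estimation-scale transforms ------------------------------------------

# Unconstrained (estimation-scale) representation used for ML fitting and
# multivariate-normal parameter sampling: log for strictly positive
# parameters, identity otherwise.

to_estimation <- function(fp) {
  def <- fam_def(fp$family)
  v <- unlist(fp$params)
  tr <- def$transform[names(v)]
  v[tr == "log"] <- log(v[tr == "log"])
  names(v) <- ifelse(tr == "log", paste0("log(", names(v), ")"), names(v))
  v
}

from_estimation <- function(family, est) {
  def <- fam_def(family)
  tr <- def$transform
  v <- as.numeric(est)
  v[tr == "log"] <- exp(v[tr == "log"])
  names(v) <- def$pars
  do.call(family_params, c(list(family = family), as.list(v)))
}

estimation_par_names <- function(family) {
  def <- fam_def(family)
  ifelse(def$transform == "log", paste0("log(", def$pars, ")"), def$pars)
}
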