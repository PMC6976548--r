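# Model-free estimators used for dataset diagnostics: the Kaplan-Meier
# product-limit survival curve with Greenwood variance, a piecewise
# (occurrence/exposure) hazard, a kernel-smoothed hazard and nonparametric
# bootstrap bands for either hazard estimator.

#' Kaplan-Meier survival estimate with Greenwood variance
#'
#' Product-limit estimate at the distinct event times, with Greenwood's
#' variance `S(t)^2 * sum_j d_j / (r_j (r_j - d_j))` and the Nelson-Aalen
#' cumulative hazard `sum_j d_j / r_j`.  Computed via
#' [survival::survfit()]; censored observations reduce the risk set without
#' introducing a step.
#'
#' @param data a [survival_data()].
#' @param level confidence level for the (plain-scale) Greenwood interval.
#' @return A data frame of class `step_survival` with columns `time`,
#'   `n_risk`, `n_event`, `surv`, `var_greenwood`, `lower`, `upper`,
#'   `cumhaz`.
#' @export
kaplan_meier <- function(data, level = 0.95) {
  data <- check_data(data)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                          conf.type = "plain", conf.int = level)
  keep <- sf$n.event > 0
  out <- data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
                    n_event = sf$n.event[keep], surv = sf$surv[keep],
                    var_greenwood = (sf$std.err[keep] * sf$surv[keep])^2,
                    lower = pmax(sf$lower[keep], 0),
                    upper = pmin(sf$upper[keep], 1),
                    cumhaz = cumsum(sf$n.event / sf$n.risk)[keep])
  structure(out, n = nrow(data), class = c("step_survival", "data.frame"))
}

new_empirical_hazard <- function(time, hazard, style, control,
                                 lower = NULL, upper = NULL) {
  df <- data.frame(time = time, hazard = hazard)
  if (!is.null(lower)) { df$lower <- lower; df$upper <- upper }
  structure(df, style = style, control = control,
            class = c("empirical_hazard", "data.frame"))
}

#' Piecewise empirical hazard
#'
#' Occurrence/exposure rates over `n_intervals` equal-width intervals
#' spanning `(0, max follow-up]`: events in the interval divided by
#' person-time at risk accrued inside it.  Intervals with no person-time
#' are reported as `NA`, not zero.  With a single interval the estimate
#' reduces to the closed-form exponential rate `N_events / sum(t_i)`.
#'
#' @param data a [survival_data()].
#' @param n_intervals number of equal-width intervals (default 25).
#' @param breaks optional explicit interval breaks (used e.g. by the
#'   bootstrap to hold the grid fixed across resamples).
#' @return An `empirical_hazard` data frame with columns `time` (interval
#'   midpoints), `hazard`, plus attributes holding the interval breaks.
#' @export
piecewise_hazard <- function(data, n_intervals = 25, breaks = NULL) {
  data <- check_data(data)
  if (n_intervals < 1)
    hazext_error("`n_intervals` must be >= 1", "hazext_usage_error")
  breaks <- breaks %||% seq(0, max(data$time), length.out = n_intervals + 1)
  n_intervals <- length(breaks) - 1L
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  events <- person_time <- numeric(n_intervals)
  for (k in seq_len(n_intervals)) {
    events[k] <- sum(data$event == 1 & data$time > lo[k] & data$time <= hi[k])
    person_time[k] <- sum(pmax(pmin(data$time, hi[k]) - lo[k], 0))
  }
  hzd <- ifelse(person_time > 0, events / person_time, NA_real_)
  out <- new_empirical_hazard((lo + hi) / 2, hzd, "piecewise",
                              list(n_intervals = n_intervals))
  attr(out, "breaks") <- breaks
  attr(out, "events") <- events
  attr(out, "person_time") <- person_time
  out
}

epanechnikov <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)

#' Kernel-smoothed empirical hazard
#'
#' Ratio-type kernel hazard estimator with an Epanechnikov kernel: at each
#' evaluation point the hazard is the kernel-smoothed event count divided by
#' the kernel-smoothed person-time at risk,
#' `sum_i delta_i K_b(t0 - t_i) / integral K_b(t0 - u) Y(u) du`,
#' where `Y(u)` is the number at risk.  Because the same kernel truncation
#' applies to numerator and denominator, the estimator is approximately
#' boundary-corrected near 0 and the maximum follow-up.  The evaluation grid
#' is interior (half a bandwidth in from each end).
#'
#' @param data a [survival_data()].
#' @param bandwidth kernel half-width in years; `NULL` (default) uses
#'   follow-up range / 8.  Bandwidths above half the follow-up range are
#'   clamped with a warning.
#' @param n_grid number of evaluation points.
#' @param eval_times optional explicit evaluation grid (held fixed by the
#'   bootstrap across resamples).
#' @return An `empirical_hazard` data frame (style `"smoothed"`).
#' @export
smoothed_hazard <- function(data, bandwidth = NULL, n_grid = 51,
                            eval_times = NULL) {
  data <- check_data(data)
  tmax <- max(data$time)
  b <- bandwidth %||% (tmax / 8)
  if (b <= 0)
    hazext_error("`bandwidth` must be positive", "hazext_usage_error")
  if (b > tmax / 2) {
    warning("bandwidth exceeds half the follow-up range; clamping")
    b <- tmax / 2
  }
  eval_t <- eval_times %||% seq(b / 2, tmax - b / 2, length.out = n_grid)
  if (n_events(data) == 0)
    return(new_empirical_hazard(eval_t, rep(0, length(eval_t)), "smoothed",
                                list(bandwidth = b)))
  t_ev <- data$time[data$event == 1]
  # number at risk Y(u) on a fine grid (risk set = subjects with t_i >= u)
  fine <- seq(0, max(tmax, max(eval_t)), length.out = 512)
  Yfun <- stats::ecdf(data$time)
  Y <- nrow(data) * (1 - Yfun(fine - 1e-9 * tmax))
  du <- fine[2] - fine[1]
  hzd <- vapply(eval_t, function(t0) {
    num <- sum(epanechnikov((t0 - t_ev) / b)) / b
    den <- sum(epanechnikov((t0 - fine) / b) / b * Y) * du
    if (den <= 0) NA_real_ else num / den
  }, numeric(1))
  new_empirical_hazard(eval_t, hzd, "smoothed", list(bandwidth = b))
}

#' Bootstrap confidence band for an empirical hazard estimator
#'
#' Nonparametric case resampling: subjects' `(time, event)` pairs are drawn
#' with replacement, the estimator is re-evaluated on a fixed grid, and the
#' pointwise 2.5/97.5 percentile band is attached to the point estimate.
#' Replicates where the estimator fails are dropped (counted on the result);
#' more than 10% failures is an error.
#'
#' @param data a [survival_data()].
#' @param estimator `"smoothed"` or `"piecewise"`, or a function
#'   `(data) -> empirical_hazard` evaluated on a fixed grid.
#' @param reps bootstrap replicates (default 500).
#' @param seed integer seed for reproducibility.
#' @param level confidence level.
#' @param ... passed to the built-in estimator.
#' @return The point-estimate `empirical_hazard` with `lower`/`upper`
#'   columns and attributes `reps_used`, `reps_failed`.
#' @export
bootstrap_hazard_band <- function(data, estimator = c("smoothed", "piecewise"),
                                  reps = 500, seed = DEFAULT_SEED,
                                  level = 0.95, ...) {
  data <- check_data(data)
  if (reps < 100)
    hazext_error("`reps` must be at least 100", "hazext_usage_error")
  if (is.character(estimator)) {
    estimator <- match.arg(estimator)
    fixed <- list(...)
    est_fun <- if (estimator == "smoothed") {
      b <- fixed$bandwidth %||% (max(data$time) / 8)
      grid0 <- smoothed_hazard(data, bandwidth = b)$time
      function(d) smoothed_hazard(d, bandwidth = b, eval_times = grid0)
    } else {
      brk <- piecewise_hazard(data,
                              n_intervals = fixed$n_intervals %||% 25)
      function(d) piecewise_hazard(d, breaks = attr(brk, "breaks"))
    }
  } else est_fun <- estimator
  point <- est_fun(data)
  n <- nrow(data)
  boot <- with_local_seed(seed, {
    lapply(seq_len(reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- survival_data(data$time[idx], data$event[idx])
      tryCatch(est_fun(d)$hazard, error = function(e) NULL)
    })
  })
  failed <- sum(vapply(boot, is.null, logical(1)))
  if (failed > 0.1 * reps)
    hazext_error(sprintf("%d/%d bootstrap replicates failed", failed, reps),
                 "hazext_bootstrap_error")
  M <- do.call(cbind, boot[!vapply(boot, is.null, logical(1))])
  alpha <- (1 - level) / 2
  qs <- apply(M, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)
  point$lower <- qs[1, ]
  point$upper <- qs[2, ]
  attr(point, "reps_used") <- reps - failed
  attr(point, "reps_failed") <- failed
  point
}
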