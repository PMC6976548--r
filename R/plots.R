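# Base-graphics plotting.  Plots are a secondary artifact: every plotted
# number is available from the tidy exports first.

#' @export
plot.curve_estimate <- function(x, log_hazard = TRUE, ...) {
  q <- attr(x, "quantity")
  ylog <- q == "hazard" && log_hazard && all(x$lower > 0)
  graphics::plot(x$time, x$point, type = "l", lwd = 2,
                 log = if (ylog) "y" else "",
                 ylim = range(x$lower, x$upper, x$point, finite = TRUE),
                 xlab = "time (years)", ylab = q, ...)
  graphics::lines(x$time, x$lower, lty = 3)
  graphics::lines(x$time, x$upper, lty = 3)
  graphics::abline(v = attr(x, "observed_end"), lty = 2, col = "grey40")
  invisible(x)
}

# internal: plot one family/quantity block of a tidy curve data frame
plot_curve_df <- function(df, main = "", observed_end = NULL) {
  graphics::plot(df$time, df$point, type = "l", lwd = 2,
                 ylim = range(df$lower, df$upper, finite = TRUE),
                 xlab = "time (years)", ylab = df$quantity[1], main = main)
  graphics::lines(df$time, df$lower, lty = 3)
  graphics::lines(df$time, df$upper, lty = 3)
  if (!is.null(observed_end))
    graphics::abline(v = observed_end, lty = 2, col = "grey40")
  invisible(df)
}

#' @export
plot.step_survival <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 lwd = 2, xlab = "time (years)", ylab = "survival",
                 ylim = c(0, 1), main = "Kaplan-Meier", ...)
  graphics::lines(stats::stepfun(x$time, c(1, x$lower)), do.points = FALSE,
                  lty = 3)
  graphics::lines(stats::stepfun(x$time, c(1, x$upper)), do.points = FALSE,
                  lty = 3)
  invisible(x)
}

#' @export
plot.empirical_hazard <- function(x, ...) {
  has_band <- all(c("lower", "upper") %in% names(x))
  ylim <- if (has_band) range(x$lower, x$upper, x$hazard, na.rm = TRUE)
          else range(x$hazard, na.rm = TRUE)
  if (attr(x, "style") == "piecewise") {
    graphics::plot(x$time, x$hazard, type = "s", lwd = 2, ylim = ylim,
                   xlab = "time (years)", ylab = "hazard", ...)
  } else {
    graphics::plot(x$time, x$hazard, type = "l", lwd = 2, ylim = ylim,
                   xlab = "time (years)", ylab = "hazard", ...)
  }
  if (has_band) {
    graphics::lines(x$time, x$lower, lty = 3)
    graphics::lines(x$time, x$upper, lty = 3)
  }
  invisible(x)
}

#' Dataset diagnostics panel
#'
#' Kaplan-Meier survival plus smoothed and piecewise empirical hazards for
#' one dataset, the standard exploratory view before choosing an
#' extrapolation model.
#'
#' @param data a [survival_data()].
#' @param bootstrap_reps if > 0, adds a bootstrap band to the smoothed
#'   hazard.
#' @param seed seed for the bootstrap band.
#' @return Invisibly, a list of the three estimates plotted.
#' @export
plot_dataset_diagnostics <- function(data, bootstrap_reps = 0,
                                     seed = DEFAULT_SEED) {
  data <- check_data(data)
  km <- kaplan_meier(data)
  sm <- if (bootstrap_reps > 0)
    bootstrap_hazard_band(data, "smoothed", reps = bootstrap_reps,
                          seed = seed)
  else smoothed_hazard(data)
  pw <- piecewise_hazard(data)
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  plot(km)
  plot(sm, main = "smoothed hazard")
  plot(pw, main = "piecewise hazard")
  invisible(list(km = km, smoothed = sm, piecewise = pw))
}
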