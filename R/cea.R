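# Hypothetical two-state ("well"/"dead") Markov cohort cost-effectiveness
# model driven by a fitted survival model.  The control arm's weekly death
# probabilities come from the fitted cumulative hazard; the intervention
# applies a hazard ratio directly to that hazard.  Utilities are 1 (well) and
# 0 (dead); the control costs 100 pounds every 2 weeks and the intervention an
# additional 100 pounds every 2 weeks, both accrued while alive.  Horizon 10
# years, weekly cycles, no discounting.

#' Markov cost-effectiveness model specification
#'
#' @param horizon_years decision horizon (default 10).
#' @param cycle_weeks cycle length in weeks (default 1).
#' @param cost_control_2wk control-arm cost per 2 weeks alive (default 100).
#' @param cost_intervention_extra_2wk additional intervention cost per
#'   2 weeks alive (default 100).
#' @param hazard_ratio intervention hazard ratio applied directly to the
#'   fitted control hazard (default 0.75).
#' @param utility_well,utility_dead state utilities (defaults 1 and 0).
#' @param half_cycle if `TRUE`, state membership for QALY and cost accrual
#'   is the average of cycle-start and cycle-end occupancy; default `FALSE`
#'   (membership at cycle start).
#' @param wtp_grid willingness-to-pay grid in pounds per QALY; includes
#'   20000 by default.
#' @return An object of class `markov_spec`.
#' @export
markov_spec <- function(horizon_years = 10, cycle_weeks = 1,
                        cost_control_2wk = 100,
                        cost_intervention_extra_2wk = 100,
                        hazard_ratio = 0.75,
                        utility_well = 1, utility_dead = 0,
                        half_cycle = FALSE,
                        wtp_grid = seq(0, 50000, by = 2500)) {
  assert_number(horizon_years, "horizon_years", 0, strict = TRUE)
  assert_number(cycle_weeks, "cycle_weeks", 0, strict = TRUE)
  assert_number(hazard_ratio, "hazard_ratio", 0, strict = TRUE)
  assert_number(cost_control_2wk, "cost_control_2wk", 0)
  assert_number(cost_intervention_extra_2wk, "cost_intervention_extra_2wk", 0)
  n_cycles <- horizon_years * 52 / cycle_weeks
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    hazext_error("horizon must be an integral number of cycles",
                 "hazext_usage_error")
  structure(list(horizon_years = horizon_years, cycle_weeks = cycle_weeks,
                 n_cycles = as.integer(round(n_cycles)),
                 cycle_years = cycle_weeks / 52,
                 cost_control_wk = cost_control_2wk / 2,
                 cost_intervention_wk =
                   (cost_control_2wk + cost_intervention_extra_2wk) / 2,
                 hazard_ratio = hazard_ratio,
                 utility_well = utility_well, utility_dead = utility_dead,
                 half_cycle = half_cycle, wtp_grid = wtp_grid),
            class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  cat(sprintf(
    "<markov_spec> %g y horizon, %g-week cycles (%d), HR %g, costs %g/%g per week, half-cycle %s\n",
    x$horizon_years, x$cycle_weeks, x$n_cycles, x$hazard_ratio,
    x$cost_control_wk, x$cost_intervention_wk, x$half_cycle))
  invisible(x)
}

#' Per-cycle death probabilities from a fitted model
#'
#' For cycle `k` spanning `[t_k, t_{k+1})` the death probability is
#' `1 - exp(-hr * (H(t_{k+1}) - H(t_k)))` with `H` the fitted cumulative
#' hazard, so the hazard ratio acts directly on the hazard.
#'
#' @param fit a [hazext_fit] (or a [family_params()]).
#' @param spec a [markov_spec()].
#' @param hr hazard ratio (1 for the control arm).
#' @return Vector of `spec$n_cycles` probabilities in `[0, 1]`.
#' @export
cycle_death_probs <- function(fit, spec, hr = 1) {
  fp <- if (inherits(fit, "hazext_fit")) fit$fp else check_fp(fit)
  bounds <- seq(0, spec$horizon_years, length.out = spec$n_cycles + 1)
  H <- cumhaz(fp, bounds)
  if (any(!is.finite(H)))
    hazext_error(sprintf("non-finite cumulative hazard at cycle %d",
                         which(!is.finite(H))[1] - 1L),
                 "hazext_domain_error")
  dH <- pmax(diff(H), 0)
  -expm1(-hr * dH)
}

#' Run the two-state Markov cohort model for one arm
#'
#' Starts the cohort fully in the "well" state and applies the per-cycle
#' death probabilities.  QALYs are alive time weighted by the well-state
#' utility; costs accrue at the arm's weekly rate while alive.  By default
#' accrual uses state membership at cycle start; `spec$half_cycle = TRUE`
#' averages start and end occupancy.
#'
#' @param spec a [markov_spec()].
#' @param death_probs per-cycle death probabilities (length
#'   `spec$n_cycles`).
#' @param cost_per_week the arm's cost per week alive.
#' @return List with `qalys`, `costs`, `life_years`.
#' @export
run_markov <- function(spec, death_probs, cost_per_week) {
  if (length(death_probs) != spec$n_cycles)
    hazext_error("need one death probability per cycle",
                 "hazext_usage_error")
  if (any(death_probs < 0 | death_probs > 1 | !is.finite(death_probs)))
    hazext_error("death probabilities must lie in [0, 1]",
                 "hazext_usage_error")
  alive_start <- cumprod(c(1, 1 - death_probs))[seq_len(spec$n_cycles)]
  membership <- if (spec$half_cycle)
    alive_start * (1 - death_probs / 2) else alive_start
  life_years <- sum(membership) * spec$cycle_years
  list(qalys = life_years * spec$utility_well,
       costs = sum(membership) * spec$cycle_weeks * cost_per_week,
       life_years = life_years)
}

arm_outcomes <- function(fp, spec) {
  pc <- cycle_death_probs(fp, spec, hr = 1)
  pi_ <- cycle_death_probs(fp, spec, hr = spec$hazard_ratio)
  ctrl <- run_markov(spec, pc, spec$cost_control_wk)
  intv <- run_markov(spec, pi_, spec$cost_intervention_wk)
  c(cost_control = ctrl$costs, qaly_control = ctrl$qalys,
    cost_intervention = intv$costs, qaly_intervention = intv$qalys)
}

#' Probabilistic sensitivity analysis for one survival model
#'
#' Each PSA draw samples a parameter vector through the multivariate-normal
#' mechanism of [mvn_parameter_draws()], rebuilds both arms' Markov traces
#' and records costs and QALYs.  The summary ICER is the ratio of mean
#' incremental costs to mean incremental QALYs.  The ICER confidence
#' interval reported by [summary.psa_result()] is the percentile interval of
#' the per-draw `delta-cost / delta-QALY` ratios (a convention that must be
#' kept in mind when per-draw incremental QALYs approach zero).
#'
#' @param fit a [hazext_fit] for the control-arm hazard.
#' @param spec a [markov_spec()].
#' @param n_samples PSA draws (default 1000).
#' @param seed integer seed.
#' @return An object of class `psa_result`: per-draw outcome matrix,
#'   deterministic (point-estimate) outcomes, ICER, and the spec.
#' @export
run_psa <- function(fit, spec = markov_spec(), n_samples = 1000,
                    seed = DEFAULT_SEED) {
  check_fit(fit)
  if (n_samples < 2)
    hazext_error("`n_samples` must be >= 2", "hazext_usage_error")
  draws <- mvn_parameter_draws(fit, n_samples, seed)
  M <- t(apply(draws, 1, function(est)
    arm_outcomes(from_estimation(fit$family, est), spec)))
  point <- arm_outcomes(fit$fp, spec)
  inc_cost <- M[, "cost_intervention"] - M[, "cost_control"]
  inc_qaly <- M[, "qaly_intervention"] - M[, "qaly_control"]
  structure(list(draws = as.data.frame(M), point = point,
                 inc_cost = inc_cost, inc_qaly = inc_qaly,
                 icer = mean(inc_cost) / mean(inc_qaly),
                 family = fit$family, spec = spec,
                 n_samples = n_samples, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %s model, %d draws: mean dCost %.0f, mean dQALY %.4f, ICER %.0f\n",
    x$family, x$n_samples, mean(x$inc_cost), mean(x$inc_qaly), x$icer))
  invisible(x)
}

net_benefit <- function(psa, wtp) {
  cbind(control = wtp * psa$draws$qaly_control - psa$draws$cost_control,
        intervention = wtp * psa$draws$qaly_intervention -
          psa$draws$cost_intervention)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention has the highest net benefit,
#' `wtp * QALY - cost`, across PSA draws, per willingness-to-pay value.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid willingness-to-pay values (defaults to the spec's grid).
#' @return Data frame with columns `wtp` and `p_intervention`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  wtps <- wtp_grid %||% psa$spec$wtp_grid
  p <- vapply(wtps, function(w) {
    nb <- net_benefit(psa, w)
    mean(nb[, "intervention"] >= nb[, "control"])
  }, numeric(1))
  data.frame(wtp = wtps, p_intervention = p)
}

#' Expected value of perfect information
#'
#' Per-person EVPI at willingness-to-pay `wtp`:
#' `mean_b max_s NB_bs - max_s mean_b NB_bs` with net benefit
#' `NB = wtp * QALY - cost`.  Always non-negative; exactly zero when one
#' strategy has the highest net benefit in every draw.
#'
#' @param psa a [run_psa()] result.
#' @param wtp willingness to pay per QALY (>= 0); may be a vector.
#' @return EVPI in pounds per person, one value per `wtp`.
#' @export
evpi <- function(psa, wtp = 20000) {
  if (!inherits(psa, "psa_result") || nrow(psa$draws) == 0)
    hazext_error("`psa` must be a non-empty psa_result",
                 "hazext_usage_error")
  if (any(wtp < 0))
    hazext_error("`wtp` must be non-negative", "hazext_usage_error")
  vapply(wtp, function(w) {
    nb <- net_benefit(psa, w)
    mean(pmax(nb[, 1], nb[, 2])) - max(colMeans(nb))
  }, numeric(1))
}

#' Summarise a PSA
#'
#' @param object a [run_psa()] result.
#' @param wtp willingness to pay used for the EVPI (default 20000).
#' @param ... unused.
#' @return List with deterministic outcomes, mean PSA outcomes per arm,
#'   incremental summaries, ICER with percentile CI of the per-draw ratios,
#'   CEAC and EVPI.
#' @export
summary.psa_result <- function(object, wtp = 20000, ...) {
  ratios <- object$inc_cost / object$inc_qaly
  ci <- stats::quantile(ratios, c(0.025, 0.975), names = FALSE)
  list(family = object$family,
       point = object$point,
       mean_outcomes = colMeans(object$draws),
       mean_inc_cost = mean(object$inc_cost),
       mean_inc_qaly = mean(object$inc_qaly),
       icer = object$icer,
       icer_ci = ci,
       icer_ci_width = diff(ci),
       ceac = ceac(object),
       evpi_at_wtp = stats::setNames(evpi(object, wtp), wtp),
       n_samples = object$n_samples,
       seed = object$seed)
}
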