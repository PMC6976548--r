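---
title: "Survival extrapolation and its uncertainty: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival extrapolation and its uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazext)
```

## The problem

Cost-effectiveness analyses need lifetime mean survival, but trials stop
early: the fitted hazard function must be extrapolated beyond the observed
follow-up.  Different parametric families that fit the observed data almost
equally well can extrapolate very differently — and, less appreciated, they
imply very different *uncertainty* about the extrapolated hazard: constant,
widening or narrowing over time.  `hazext` implements the machinery needed
to study this: seven parametric families, maximum-likelihood fitting under
right censoring, three uncertainty-propagation routes, model-free hazard
diagnostics, a synthetic-data generator for four canonical hazard shapes,
and a two-state Markov cost-effectiveness model with probabilistic
sensitivity analysis (PSA) and expected value of perfect information
(EVPI).

## The seven families

All families are defined through their cumulative hazard
$H(t) = -\log S(t)$, with hazard $h(t) = H'(t)$ and density
$f(t) = h(t)S(t)$.  The natural-scale parameterisations (all for
$t \ge 0$):

| family | parameters | $H(t)$ or $S(t)$ | hazard shapes |
|---|---|---|---|
| exponential | rate $\lambda>0$ | $H=\lambda t$ | constant |
| Weibull | shape $\gamma>0$, rate $\lambda>0$ | $H=\lambda t^{\gamma}$ | constant / monotone |
| Gompertz | shape $\theta\in\mathbb R$, rate $\lambda>0$ | $h=\lambda e^{\theta t}$ | constant / monotone |
| gamma | shape, rate $>0$ | standard shape–rate gamma | constant / monotone |
| log-logistic | shape $\beta>0$, rate $\alpha>0$ | $S=1/(1+(\alpha t)^{\beta})$ | decreasing / unimodal |
| log-normal | meanlog $\in\mathbb R$, sdlog $>0$ | standard log-normal | unimodal |
| generalised gamma | $\mu\in\mathbb R$, $\sigma>0$, $Q\in\mathbb R$ | Prentice form | constant / monotone / bathtub / arc |

Conversions to common software conventions are documented in
`?family_params`: the Weibull `rate` is `scale^-shape` relative to
`stats::dweibull()`, the log-logistic `rate` is `1/scale` relative to
`flexsurv::dllogis`, and the generalised gamma is exactly flexsurv's
`(mu, sigma, Q)` Prentice convention — chosen because it nests the
log-normal at $Q=0$ and a Weibull at $Q=1$ continuously, which both the
sampler (a transformed gamma variate, no rejection) and the optimiser rely
on.  A Gompertz with $\theta<0$ is improper: a fraction
$\exp(-\lambda/|\theta|)$ never experiences the event, so its unrestricted
mean diverges and `rmst()` insists on a finite horizon
(`hazext_diverging_mean_error`).

Hazards at $t=0$ return the analytic limit where finite (0 for the
log-normal; `rate` for the exponential and Gompertz) and raise a domain
error where the limit diverges (shape $<1$ Weibull/gamma/log-logistic);
evaluation grids therefore start at small positive times.

### Restricted means

`rmst(fp, horizon)` is $\int_0^{\tau} S(t)\,dt$.  Exact closed forms (via
regularised incomplete gamma/beta functions and the log-normal partial
expectation) are used for the exponential, Weibull, gamma, log-normal,
log-logistic (shape $>1$) and generalised gamma; the Gompertz and remaining
corners use adaptive quadrature with absolute tolerance $10^{-8}$
(`stats::integrate`, which also performs the change of variables for
infinite horizons).  The closed forms were preferred over
quadrature-everywhere because the Monte-Carlo uncertainty route evaluates
the restricted mean across up to $10^5$ parameter draws, and the quadrature
path remains the independent oracle in the test suite.

## Fitting

`fit_parametric()` maximises the right-censored log-likelihood
$\ell(\theta)=\sum_i\left[\delta_i\log f(t_i)+(1-\delta_i)\log
S(t_i)\right]$ on an *estimation scale*: log for strictly positive
parameters, identity for the unconstrained ones (Gompertz shape, log-normal
meanlog, generalised-gamma $\mu$ and $Q$).  This keeps every optimiser step
and every multivariate-normal parameter draw inside the family's domain,
and it is the scale on which `Var(θ̂)` is reported — a choice that
matters slightly for the shape of MVN bands and is therefore stated
explicitly here.  Ties and simultaneous censoring enter the continuous-time
likelihood as written, with no correction.

The optimiser is BFGS (`stats::optim`, relative tolerance $10^{-12}$,
up to 500 iterations) restarted from the moment-based starting values of
`start_values()` plus two jittered copies; the best optimum is kept and
optim's convergence flag is carried on the fit (a relative-tolerance
stopping rule was preferred over a fixed gradient-norm threshold because a
finite-difference gradient at $n=2000$ is noisier than the optimum itself).
The generalised gamma starts from the fitted Weibull embedding, which
guarantees its maximised likelihood dominates the Weibull's.  `Var(θ̂)` is
the inverse negative Hessian at the optimum, by central finite differences
with relative step $10^{-5}$; a singular or indefinite Hessian is an error
naming the family, never a silent `NA`.  The exponential also has
`fit_exponential_exact()`: $\hat\lambda = N_e/\sum t_i$,
$\mathrm{Var}(\hat\lambda)=\hat\lambda^2/N_e$, equivalently
$\mathrm{Var}(\log\hat\lambda)=1/N_e$.

## Three uncertainty routes

* **Exact** (`exact_exponential_uncertainty`): for the exponential the
  hazard variance is the parameter variance, constant over the whole grid —
  extrapolated uncertainty does not fan out, however far ahead one looks.
  The mean survival is $1/\hat\lambda$ with variance
  $1/(\hat\lambda^2N_e)$.
* **Delta** (`delta_variance`, `delta_curve`):
  $\mathrm{Var}(g)\approx\nabla g^{\top}\,\mathrm{Var}(\hat\theta)\,\nabla
  g$ with numeric gradients on the estimation scale.  Bands are built on a
  transformed scale (log for hazards, logit for survival) and
  back-transformed so they respect range constraints.
* **MVN Monte Carlo** (`mvn_curve`, `mean_survival`): draws
  $\theta_b\sim N(\hat\theta,\mathrm{Var}(\hat\theta))$ on the estimation
  scale, reports the variance
  $\tfrac1B\sum_b\left[g(\theta_b)-g(\hat\theta)\right]^2$ and percentile
  95% limits.  Percentile bands commute with monotone maps, so hazard bands
  are non-negative and survival bands sit in $[0,1]$ automatically.

The default $B$ is 1000 — the same sample count as the PSA, since no
separate banding sample size is canonical — and the default base seed is
20191125, recorded in outputs.  With a shared seed the hazard, survival and
mean-survival summaries of one fit reuse identical draws, so they are
coherent draw by draw.  The three routes agree for the exponential to
Monte-Carlo accuracy; for curved functionals (e.g. an extrapolated Weibull
hazard at small $n$) the MVN variance retains second-order terms the delta
linearisation drops, a gap of a few percent that shrinks with the parameter
SEs, not with $B$.  "Lifetime" mean survival defaults to the 10-year
decision horizon, with `Inf` allowed where the mean exists.

## Model-free diagnostics

`kaplan_meier()` (product-limit with Greenwood variance, via the `survival`
package), `piecewise_hazard()` (occurrence/exposure over 25 equal-width
intervals by default; empty intervals are `NA`, not 0) and
`smoothed_hazard()` (an Epanechnikov ratio estimator: smoothed event counts
over smoothed person-time at risk, evaluated on an interior grid, with
automatic bandwidth = follow-up range/8).  The kernel, bandwidth rule and
equal-width breakpoints are this package's own transparent choices — the
data-driven defaults of dedicated smoothing packages are not reproduced, so
smoothed-hazard values should be read qualitatively.  Bootstrap bands
(`bootstrap_hazard_band`, 500 case resamples by default) cover both hazard
estimators, since no analytic variance is available for them.

## The synthetic-data generator

`scenario_spec()`/`make_dataset()` regenerate four canonical single-arm
datasets: flat, increasing, decreasing and unimodal hazards.  The fixed
design is: $n=400$ subjects, every mixture component calibrated to a mean
survival of 0.9 years, administrative censoring at 1 year and no other
censoring.  The flat dataset is one exponential draw; the others are
200+200 mixtures (Weibull+gamma for the monotone shapes,
log-logistic+log-normal for the unimodal one) so that no single family
generates the data it is later fitted to.  The mixture *shape* controls are
free choices made once, on the basis that the smoothed empirical hazard of
a typical draw should show the intended shape within the observed year:
Weibull shape 2 and gamma shape 2 (increasing), Weibull shape 0.6 and gamma
shape 0.5 (decreasing), log-logistic shape 2 and log-normal sdlog 0.9
(unimodal).  They live in one block (`default_components()`) and are not
authoritative: any components with the right mean can be passed in.
`calibrate_component()` solves for the scale-type parameter analytically
wherever the mean inverts in closed form, and by root-finding for the
Gompertz.

What the generator does *not* emulate: covariates, informative or staggered
censoring, multiple hazard turning points, and the exact realisations of
any deposited case-study data — a regenerated dataset is statistically
equivalent but numerically different, so realisation-specific results
(a fitted rate of 1.16, say) are only reproduced from the original files
(see `inst/extdata/deposited/`).  Passing tests on regenerated data
therefore validates the machinery and the designs, not any particular
published number.

## The cost-effectiveness model

A two-state ("well"/"dead") Markov cohort over a 10-year horizon with
weekly cycles.  The control arm's per-cycle death probability comes from
the fitted cumulative hazard, $p_k = 1-\exp\{-\mathrm{hr}\,[H(t_{k+1}) -
H(t_k)]\}$; the intervention applies a hazard ratio of 0.75 directly to the
hazard.  Utilities are 1 (well) and 0 (dead).  Costs are £100 per 2 weeks
alive for control and an additional £100 per 2 weeks for the intervention,
implemented as weekly rates of £50 and £100.  Conventions the source
material leaves open, fixed here and flagged in outputs:

* **Accrual**: state membership at cycle *start*, no half-cycle correction
  by default (`markov_spec(half_cycle = TRUE)` switches to averaging start
  and end occupancy).  With weekly cycles the discretisation error in QALYs
  is below half a cycle (~0.01 QALY).
* **No discounting** (none is specified for the hypothetical analysis).
* **PSA**: 1000 draws by default; only the survival-model parameters are
  uncertain (costs, utilities and the hazard ratio are fixed), drawn
  through the same MVN mechanism as the curve bands.
* **ICER summary**: mean incremental cost over mean incremental QALYs.  The
  reported ICER interval is the 2.5/97.5 percentile of the per-draw
  $\Delta C_b/\Delta Q_b$ ratios — a convention that can misbehave when
  per-draw $\Delta Q$ approaches zero, which is why the CEAC and EVPI (on
  the net-benefit scale, where no ratio is involved) are reported
  alongside.  EVPI at willingness-to-pay $w$ is
  $E_b[\max_s \mathrm{NB}_{bs}] - \max_s E_b[\mathrm{NB}_{bs}]$ with
  $\mathrm{NB}=w\,\mathrm{QALY}-\mathrm{cost}$; the WTP grid always
  includes £20,000/QALY.
* Each candidate family is analysed independently; model choice is treated
  as a scenario axis, not averaged over.

## Worked example

```{r example, eval = FALSE}
d <- make_dataset(scenario_spec("increasing", seed = 1))
plot_dataset_diagnostics(d)

fit <- fit_parametric(d, "weibull")
grid <- time_grid(seq(0.05, 4, by = 0.05), observed_end = 1)
hz <- mvn_curve(fit, "hazard", grid, B = 1000)
plot(hz)                                  # log-hazard with 95% band
mean_survival(fit, horizon = 10)

psa <- run_psa(fit, markov_spec(), n_samples = 1000)
summary(psa, wtp = 20000)
```

## Numerical choices and test scale

Quadrature tolerance $10^{-8}$ (absolute); Hessian steps $10^{-5}$
relative; delta-method gradient steps $10^{-6}$ relative; hazard limits at
$t=0$ as described above; the identity $H=-\log S$ is verified to
$10^{-8}$ wherever $S>10^{-12}$ (below that, $\log S$ itself underflows in
double precision).  The test suite validates parameter recovery with 200
replicates per family at $n=2000$ (92–98% Wald coverage accepted), method
agreement at $B=10^5$ draws, and generator calibration on a regenerated
sample of 200,000 latent times — sizes chosen so each property is tested at
Monte-Carlo error well below its tolerance while the whole suite stays
routinely runnable.

## Known limitations

Single-arm, no covariates; no spline/fractional-polynomial or piecewise
hazard models; no generalised-F family (its estimation is fragile enough
that it is out of scope here); no Bayesian estimation or model averaging;
no EVPPI/EVSI.  Empirical smoothed-hazard values depend on this package's
kernel and bandwidth choices, and deposited-data replication requires the
one-time conversion described in `inst/extdata/deposited/README.md`.
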