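# hazext — uncertainty in extrapolated parametric survival models

Cost-effectiveness analyses need *lifetime* mean survival, but trials stop
early, so the fitted hazard function h(t) must be extrapolated beyond the
observed follow-up.  The choice of parametric family then drives not only
the extrapolated point estimates but also how their **uncertainty** behaves
over the extrapolated period — constant, fanning out, or (perhaps
implausibly) narrowing.  `hazext` is a toolkit for health-economic
modellers and biostatisticians to quantify and compare that uncertainty
across models.

It provides:

* **Seven survival families** — exponential, Weibull, Gompertz, gamma,
  log-logistic, log-normal, generalised gamma — defined through
  H(t) = −log S(t), with hazards, log-densities, exact samplers and
  (restricted) mean survival `rmst()` (closed forms where they exist,
  adaptive quadrature otherwise).
* **Maximum-likelihood fitting under right censoring**
  (`fit_parametric()`), on an unconstrained estimation scale (log for
  positive parameters), with Var(θ̂) from the inverse negative Hessian; the
  exponential also has the exact solution `fit_exponential_exact()`
  (λ̂ = N_e/Σt_i, Var(λ̂) = λ̂²/N_e).
* **Three uncertainty-propagation routes** for hazard, survival and mean
  survival: exact (exponential — the hazard band has constant width at all
  times), the delta method Var(g) ≈ ∇gᵀ Var(θ̂) ∇g, and the
  multivariate-normal Monte-Carlo method: θ_b ~ N(θ̂, Var(θ̂)),
  Var(g) ≈ (1/B) Σ_b [g(θ_b) − g(θ̂)]², percentile 95% bands.
* **Model-free diagnostics**: Kaplan–Meier with Greenwood variance,
  piecewise (occurrence/exposure) and kernel-smoothed hazards, bootstrap
  bands.
* **A synthetic-data generator** for four canonical single-arm datasets
  (flat, increasing, decreasing, unimodal hazards; n = 400, component mean
  survival 0.9 years, administrative censoring at 1 year, 200+200
  mixtures).
* **A two-state Markov cost-effectiveness model** (10-year horizon, weekly
  cycles, hazard ratio 0.75, £100/2-weeks costs) with PSA, ICER, CEAC and
  per-person EVPI.

## Worked example

```r
library(hazext)

d <- make_dataset(scenario_spec("increasing", seed = 1))
#> <survival_data> n = 400, events = 269, censored = 131, max follow-up = 1

fit <- fit_parametric(d, "weibull")
#> <hazext_fit> weibull (mle), n = 400, events = 269, logLik = -239.074
#>       estimate est.scale se.est.scale
#> shape  1.77747   0.57519      0.05464
#> rate   1.09954   0.09489      0.06283

mvn_curve(fit, "hazard", time_grid(c(0.5, 1, 2, 4), observed_end = 1), B = 1000)
#> <curve_estimate> hazard, method = mvn, 4 times (observed to 1)
#>   time    point         se     lower    upper
#> 1  0.5 1.140178 0.07054024 0.9996301 1.282561
#> 2  1.0 1.954409 0.18515659 1.6199382 2.344478
#> 3  2.0 3.350102 0.52518432 2.4939021 4.518641
#> 4  4.0 5.742497 1.31928017 3.8118222 8.947413

mean_survival(fit, horizon = 10)
#> <mean_survival_estimate> 0.8436 years (se 0.0307, 95% CI 0.7889-0.9106), horizon 10, method mvn

psa <- run_psa(fit, markov_spec(), n_samples = 1000)
#> <psa_result> weibull model, 1000 draws: mean dCost 2999, mean dQALY 0.1491, ICER 20117
evpi(psa, 20000)
#> [1] 45.26
```

Reading the output: the fitted Weibull hazard *increases* (shape 1.78 > 1)
and its standard error grows from 0.07 at 6 months (observed period) to
1.32 at 4 years (extrapolated) — this model's extrapolation uncertainty
fans out.  Restricting to a 10-year horizon, mean survival is 0.84 years
(se 0.03).  Driving the Markov model with this hazard, the intervention
(hazard ratio 0.75, +£100 per 2 weeks) costs £20,117 per QALY gained; at a
willingness to pay of £20,000/QALY the decision is borderline (CEAC 0.43)
and perfect information about the model's parameters would be worth about
£45 per person.  Repeating with `"gompertz"`, `"loglogistic"`, … shows how
strongly these conclusions depend on the family chosen.

The full case-study pipeline is available as functions
(`cmd_simulate()`, `cmd_fit_extrapolate()`, `cmd_cea()` over a YAML
config) and as a thin CLI (`inst/cli/hazext.R`).  See the vignette
`vignettes/extrapolation-uncertainty.Rmd` for the methods and every
numerical convention.

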