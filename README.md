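# pemfrail

Piecewise exponential hazard models with gamma frailty for recurrent
time-to-event data on the "job clock" — built for the occupational-injury
question *does experience on a job change the hazard of acute injury?*

When time-to-injury is itself the measure of experience, the baseline hazard
λ₀(t) is the parameter of interest and Cox models (which profile it out) do
not apply. pemfrail estimates and compares parametric baselines under
proportional covariate effects λᵢ(t) = λ₀(t)·exp(xᵢ′β):

* **exponential** — λ₀(t) = λ, the null that experience does not matter;
* **Weibull** — λ₀(t) = λ·p·t^(p−1), the exponential at shape p = 1;
* **K-piece exponential** — constant on pieces (τₖ₋₁, τₖ], free to jump at
  the cuts, fitted through its Poisson-regression equivalence (events on
  piece dummies + covariates with a log-exposure offset).

A worker-specific gamma frailty u (mean 1, variance θ) multiplies the hazard
to absorb within-worker correlation of recurrent injuries; the marginal
likelihood is maximized directly. Around the models sit the full analysis
machinery: counting-process data handling with exact episode splitting,
data-driven changepoint estimation by profile likelihood with an
employee-level bootstrap, a learning/test model-selection pipeline (LRT for
nested pairs, BIC and Schwarz Bayes factors otherwise), fully-conditional
multiple imputation with Rubin pooling for incomplete covariates, a
synthetic cohort generator with known truth, and a command-line interface
(`inst/cli/pemfrail`).

## Worked example

Simulate a 2,000-worker cohort (two-piece truth: hazard drops by the factor
1.32 after 12 months; θ = 0.5) and fit the hypothesis-driven two-piece
frailty model:

```r
library(pemfrail)
sim <- simulate_cohort(simulation_design(n_subjects = 2000, seed = 42))
sim$cohort
#> <cohort> 5606 episodes, 4631 jobs, 2000 subjects; 975 events over 210709.4 person-months

fit <- fit_model(hazard_spec("pem", piece_grid(12),
                             covariates = c("male", "phys_demand"),
                             frailty = TRUE), sim$cohort)
hazard_ratio_table(fit)
#>          term    hr conf_low conf_high  p_value
#> 1  piece_0_12 1.221    1.059     1.408 5.93e-03
#> 2        male 0.817    0.689     0.968 1.98e-02
#> 3 phys_demand 1.321    1.239     1.408 1.34e-17
```

`piece_0_12` is the "inexperienced-period" hazard ratio: the first year on a
job carries a ~22% higher injury hazard than the experienced period in this
draw (the generating truth for this contrast is 1.32; the fitted model
adjusts for two of the six generated covariates, and hazard ratios are
conditional on the frailty). `frailty_variance(fit)` returns θ̂ = 0.43, and

```r
predict_survival(fit, covariates = c(male = 1, phys_demand = 0),
                 times = c(6, 12, 24))
#>   time  surv
#> 1    6 0.973
#> 2   12 0.947
#> 3   24 0.905
```

gives the model-implied injury-free curve. The data-driven changepoint and
the selection pipeline are one call each: `profile_changepoint(x)` and
`run_selection_pipeline(x, pipeline_config(...))`.

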