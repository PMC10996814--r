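# hybridsurv

Hybrid mechanistic–neural survival modeling for immunotherapy cohorts.

Serial imaging of patients on immune checkpoint inhibitors yields
normalized tumor-burden trajectories. `hybridsurv` fits each patient's
trajectory with a logistic-form ordinary differential equation,

dρ/dt = (α₀ − μ + Λμ)ρ − Λμρ²,  ρ(0) = 1,

whose parameters are interpretable mathematical biomarkers: the tumor
kill rate `μ`, the anti-tumor immune state `Λ`, and the growth rate at
first restaging `α₁ = ln ρ(t₁)/t₁` (patients with `α₁ ≤ 0.002/day`
form the favorable prognostic group). These biomarkers are then fed,
together with standard clinical covariates, into a discrete-time
logistic-hazard neural network that predicts each patient's survival
curve. The package implements the full workflow:

- **Mechanistic fitting** — closed-form ODE solutions, multi-start
  least-squares parameter recovery on the log-burden scale, and the
  `α₁` prognostic classifier (`solve_tumor_burden()`,
  `fit_mechanistic_params()`, `fit_biomarkers()`).
- **Synthetic cohorts** — a generator calibrated to the published
  summary statistics of a 93-patient immunotherapy cohort, with a
  configurable discrete ground-truth hazard for validation studies
  (`cohort_spec()`, `generate_cohort()`, `fit_discrete_hazard_glm()`).
- **Survival network** — a single-hidden-layer logistic-hazard network
  (batch normalization, dropout, Adam, early stopping) written in base
  R with exact manual backpropagation (`network_config()`,
  `train_hazard_net()`, `predict_survival()`).
- **Evaluation** — event-time concordance, IPCW-weighted integrated
  Brier score and binomial log-likelihood against Kaplan–Meier
  censoring weights (`concordance_td()`, `brier_ipcw()`,
  `nbll_ipcw()`, `metric_report()`).
- **Interpretation** — permutation importance, feature ablation and
  integrated gradients with cross-method rank agreement
  (`permutation_importance()`, `integrated_gradients()`,
  `rank_report()`).
- **Orchestration** — one-call experiments comparing the hybrid,
  clinical-only and biomarkers-only feature sets on a shared split,
  plus exhaustive ordered k-fold stability analysis
  (`run_experiment()`, `compare_feature_sets()`, `run_kfold()`).

## Worked example

```r
library(hybridsurv)

# Mechanistic model: a treated patient whose burden shrinks to a plateau
params <- mechanistic_params(alpha0 = 0.02, mu = 0.05, Lambda = 0.8)
solve_tumor_burden(params, c(0, 60, 120, 180))
#> [1] 1.0000 0.4249 0.3230 0.2854

a1 <- compute_alpha1(0.4249, 60)
c(alpha1 = signif(a1, 3), group = classify_alpha1(a1))
#>   alpha1    group
#> "-0.0143" "favorable"

# A calibrated 93-patient synthetic cohort, then the three-arm study
gen <- generate_cohort(cohort_spec(n_patients = 93, seed = 1))
report <- run_experiment(gen$cohort, seed = 1)
compare_feature_sets(report)
#>     feature_set c_index_td   ibs inbll
#> 1        hybrid      0.607 0.253 0.760
#> 2 clinical_only      0.721 0.258 0.764
#> 3       mb_only      0.750 0.145 0.454

# Predicted survival at 180 days for the first test patients
surv_at(report$hybrid$prediction, 180)[1:3]
#> [1] 0.526 0.500 0.260
```

At the 93-patient scale a single 59/15/19 split is noise-dominated;
repeating the comparison over 10 seeds (see
`analysis/04_compare_feature_sets.R`) gives median test C-indexes of
0.75 (biomarkers only), 0.69 (hybrid) and 0.57 (clinical only) on this
cohort: the three mechanistic biomarkers carry most of the prognostic
signal, and clinical covariates alone trail far behind. On larger
cohorts (600 patients), where the network can exploit the additional
clinical signal, the hybrid arm dominates both ablations (median
C-index 0.73 vs 0.70 and 0.57; see `tests/testthat/test-acceptance.R`).

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "hybridsurv", load_package = "installed")'
```

The suite checks every numerical component against independent
oracles: the closed-form ODE solution against adaptive numerical
integration (`deSolve`), the network gradients against finite
differences, the discrete hazard loss against expanded per-interval
cross-entropy, the IPCW metrics against brute-force term enumeration,
and the cohort generator against a discrete-hazard GLM that must
recover the generating coefficients.

See `vignettes/hybrid-survival-methods.Rmd` for the full methods
description, including the generator's calibration targets and known
limitations.
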