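# mortdomains

Explainable mortality prediction for ageing-survey cohorts: train a
suite of classifiers on a domain-structured risk-factor table, evaluate
them under seed replication with PR-AUC–centric metrics, decompose
predictive performance into **domain-level importances** by exhaustive
coalition retraining, and decompose individual predictions into
per-risk-factor **mean |SHAP|** summaries, overall and by age group.

The package is aimed at social epidemiologists and biostatisticians
working with harmonized ageing surveys (one row per respondent, a
binary death-within-window outcome, risk factors grouped into domains
such as demography, socioeconomic status, psychology, social
connections, childhood/adulthood adversity and health behaviors).
Because such extracts are typically restricted-access, a
synthetic-cohort generator with *planted, analytically known* domain
effects ships with the package, so the whole pipeline is testable as a
parameter-recovery problem.

## The core algorithm

Let `D` be the set of domains and `v(S)` the held-out test metric
(PR-AUC by default) of a model retrained on exactly the features of the
domains in coalition `S ⊆ D`. All `2^|D| − 1` non-empty coalitions
(127 for seven domains) are evaluated on a common split, and the
importance of domain `d` is the mean of its marginal contributions over
every coalition not containing it:

    I_d = 2^{-(|D|-1)} * Σ_{S ⊆ D∖{d}} [ v(S ∪ {d}) − v(S) ]

with `v(∅)` fixed at the metric's no-information value (test prevalence
for PR-AUC, 0.5 for ROC-AUC, 0 for R² and IMV). A Shapley-weighted
variant (`weighting = "shapley"`), under which `Σ_d I_d = v(D) − v(∅)`
exactly, is available.

Model evaluation uses ROC-AUC, average-precision PR-AUC, binary R²,
Efron's pseudo-R², and the Inter-Model Vigorish
`IMV = (w₁ − w₀)/w₀`, where `w` solves
`w·ln w + (1−w)·ln(1−w) = mean log-likelihood`. Per-prediction
attribution uses exact path-dependent TreeSHAP (double-precision
compiled implementation) on the log-odds scale.

See `vignettes/mortdomains-methods.Rmd` for the full methods account.

## Worked example

```r
library(mortdomains)

## a survey-scale synthetic cohort with planted domain effects
spec <- recovery_spec(n = 4000, seed = 1)
gen  <- generate_cohort(spec)
gen$table
#> <cohort_table> 4000 individuals, 44 risk factors, prevalence 0.294

gen$truth$ranking   # analytic ground truth, strongest domain first
#> [1] "demography"  "socioeconomic"  "psychology"  "social_connections"
#> [5] "childhood_adversity"  "adulthood_adversity"  "health_behaviors"

## seed-replicated evaluation of the boosted-tree model vs the
## age+gender benchmark
evaluate_suite(list(gbm_leafwise = model_spec("gbm_leafwise")),
               gen$table, split_spec(), seeds = 1:3)
#> <metric_report>
#>         model    metric     mean (se) n_seeds
#>     benchmark       imv 0.175 (0.000)       3
#>     benchmark    pr_auc 0.653 (0.004)       3
#>     benchmark pseudo_r2 0.284 (0.003)       3
#>     benchmark        r2 0.284 (0.003)       3
#>     benchmark   roc_auc 0.825 (0.000)       3
#>  gbm_leafwise       imv 0.277 (0.006)       3
#>  gbm_leafwise    pr_auc 0.850 (0.005)       3
#>  gbm_leafwise pseudo_r2 0.513 (0.012)       3
#>  gbm_leafwise        r2 0.513 (0.012)       3
#>  gbm_leafwise   roc_auc 0.927 (0.003)       3
#> IP (in-sample prevalence): 0.294

## leave-one-domain-out coalition analysis (127 retrained models)
dom <- run_domain_analysis(gen$table, gen$map, seeds = 1)
dom$importance
#>                domain importance se n_seeds       weighting metric
#> 1          demography    0.33251  0       1 unweighted_mean pr_auc
#> 2       socioeconomic    0.13923  0       1 unweighted_mean pr_auc
#> 3          psychology    0.02671  0       1 unweighted_mean pr_auc
#> 4 childhood_adversity    0.01563  0       1 unweighted_mean pr_auc
#> 5  social_connections    0.01484  0       1 unweighted_mean pr_auc
#> 6 adulthood_adversity    0.00884  0       1 unweighted_mean pr_auc
#> 7    health_behaviors    0.00393  0       1 unweighted_mean pr_auc

## SHAP decomposition over the full cohort (train + test)
parts <- split_cohort(gen$table, split_spec(seed = 1))
fit   <- fit_model(model_spec("gbm_leafwise", seed = 1), parts$train)
shap  <- compute_shap(fit, gen$table)
head(mean_abs_shap(shap), 5)
#>   feature mean_abs_shap rank above_threshold
#> 1     age         2.175    1            TRUE
#> 2  ses_01         0.486    2            TRUE
#> 3  dem_01         0.451    3            TRUE
#> 4  female         0.299    4            TRUE
#> 5  ses_07         0.289    5            TRUE
```

Reading the output: the boosted model's PR-AUC of 0.850 is nearly
triple the 0.294 prevalence baseline (the "IP" row) and clearly above
the 0.653 of the demographic benchmark, so the non-demographic domains
carry real signal. The coalition analysis attributes most of the
PR-AUC to demography and socioeconomic status — matching the planted
ordering, whose top contributions were 9 : 4 — and the mean-|SHAP|
ranking puts age first by a wide margin (2.18 on the log-odds scale,
far above the 0.1 reporting threshold).

The same pipeline runs from a single YAML config via
`run_all(read_run_config("run.yaml"))` or the thin CLI wrapper in
`inst/cli/mortdomains` (subcommands `generate`, `evaluate`, `domains`,
`shap`, `all`). Real cohorts enter through `load_cohort(csv,
config.yaml)`; the config declares the id/outcome/age/gender columns
and the feature-to-domain assignment.

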