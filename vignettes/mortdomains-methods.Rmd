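---
title: "Domain-level importance for mortality prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level importance for mortality prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ageing-survey cohorts (one row per respondent, a few dozen harmonized
risk factors, a binary indicator of death within a follow-up window)
support two questions that are usually answered separately: *how
predictable is death* from social determinants, and *where does the
predictability come from*. `mortdomains` implements a pipeline that
answers both at once: a suite of classifiers is trained and evaluated
under seed replication; predictive performance is then decomposed at the
level of risk-factor *domains* (demography, socioeconomic status,
psychology, social connections, childhood adversity, adulthood
adversity, health behaviors) by exhaustive retraining over domain
coalitions; and individual predictions are decomposed per risk factor
with SHAP attributions, overall and by age group.

Because the harmonized survey extracts this design targets are
restricted-access, the package ships a synthetic-cohort generator that
reproduces their statistical profile (sample size around 8000–18000,
death prevalence 0.17–0.32, ages 50–100, mostly-female samples, 25–61
risk factors with within-domain correlation and item missingness) with
*planted*, analytically known domain effects. Every stage of the
pipeline is therefore testable as a parameter-recovery problem.

## Evaluation metrics

Five metrics are computed on the held-out test set of each split:

* **ROC-AUC**, computed as the normalized Mann–Whitney statistic (ties
  count one half), so it is exactly the probability that a random
  positive outranks a random negative.
* **PR-AUC**, in its average-precision form
  $\sum_k (R_k - R_{k-1})\,P_k$ over descending distinct thresholds.
  Step interpolation is used deliberately: trapezoidal interpolation of
  precision–recall curves is optimistic. The no-skill baseline of this
  metric is the outcome prevalence (a constant predictor scores exactly
  the prevalence), which is why the report carries an in-sample
  prevalence ("IP") row as the interpretation anchor.
* **R²** on binary outcomes, $1 - \sum_i (y_i - \hat p_i)^2 / \sum_i
  (y_i - \bar y)^2$, and **Efron's pseudo-R²**, which is the same
  expression evaluated on predicted probabilities. Both are exposed
  because evaluation tables conventionally list them separately; with
  Efron's definition they agree to machine precision, and the package
  asserts that identity rather than approximating some other pseudo-R².
* **IMV** (Inter-Model Vigorish). The mean Bernoulli log-likelihood
  $\bar\ell$ of a prediction vector is mapped to the *entropy-equivalent
  winning probability* $w \in [0.5, 1)$ solving
  $w\ln w + (1-w)\ln(1-w) = \bar\ell$ (bisection to $10^{-10}$;
  likelihoods worse than a coin flip clip to $w = 0.5$). The IMV of an
  enhanced prediction over a baseline is $(w_1 - w_0)/w_0$. When a
  single model is reported, the baseline is the prevalence-constant
  predictor on the same test set — the canonical null, and the choice
  that makes the IP row the natural anchor; an age–gender benchmark
  baseline is available as an option (`imv_baseline = "benchmark"`).
  Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before logs.

Splits are 7:3 by default. Whether the original analyses stratified
their splits by outcome is not documented; the package stratifies by
default because the outcome is imbalanced and PR-AUC is the primary
metric (unstratified splits add avoidable between-seed variance in the
IP baseline), and the flag is recorded in the run configuration so the
choice is always visible.

## The model suite

Twelve base classifiers mirror the conventional tabular-ML zoo: a
penalized linear classifier (`ridge_logistic`), k-nearest neighbors
(`knn`, k = 25, a √n-scale heuristic), plain logistic regression, a
CART decision tree, an RBF SVM, Gaussian naive Bayes, discrete AdaBoost
over depth-1 stumps, bagged trees (`bagging` = a forest with mtry equal
to the number of features), a random forest, extremely randomized trees,
and two gradient-boosted tree learners: `gbm_leafwise` (histogram-based,
leaf-wise growth, 31 leaves, learning rate 0.1, 100 rounds — the
LightGBM-style configuration that serves as the pipeline's workhorse)
and `xgboost` (depth-wise, depth 6). Hyperparameters are the library
defaults listed in `?model_spec` — no tuning is performed — and the
resolved values are serialized into every fitted model and the run
manifest. Forest-family learners use 200 trees as a compromise between
stability and single-core runtime.

Missing values are consumed natively by the boosted-tree learners (the
booster routes missing values along a learned default branch); all
other learners receive median imputation and standardization, fitted on
the training rows only and replayed at prediction time. Models without
native probabilities (the SVM) are calibrated with a Platt-style
sigmoid fitted to training-set margins by `glm`; the library-internal
calibration was avoided because it shuffles rows irreproducibly, and
seed-exact reproducibility is a package contract (same spec + seed ⇒
identical predictions, bit for bit).

The **benchmark** model is logistic regression on exactly age and
gender — the conventional demographic null against which the added
value of the remaining domains is judged.

The **Super Learner** is classical stacking: stratified 5-fold
out-of-fold predictions from each base learner form the meta-design,
and the meta-learner is the convex combination (non-negative weights
summing to one) minimizing Bernoulli log-loss, found by quasi-Newton
descent on a softmax parameterization from a deterministic equal-weight
start. Base learners are refit on the full training set for deployment.
Five folds keep each fold comfortably populated at survey scale.

## Leave-one-domain-out coalition importance

Let $D$ be the set of domains and $v(S)$ the test-set metric of the
coalition model retrained on exactly the features of the domains in
$S \subseteq D$. All $2^{|D|} - 1$ non-empty coalitions are enumerated
(127 for seven domains) and evaluated against the *same* split within a
seed, so marginal contributions always compare models on identical test
rows. The importance of domain $d$ is the mean of its marginal
contributions

$$ I_d = \frac{1}{2^{|D|-1}} \sum_{S \subseteq D \setminus \{d\}}
   \big[v(S \cup \{d\}) - v(S)\big], $$

read literally as the *unweighted* mean over all subsets, including the
empty one. The Shapley weighting $|S|!\,(|D|-|S|-1)!/|D|!$ is provided
as an option (`weighting = "shapley"`); under it the importances sum
exactly to $v(D) - v(\varnothing)$, which the test suite asserts at
$10^{-10}$, and on additive value functions the two weightings coincide
exactly. The default is the unweighted mean because that is the stated
definition of the procedure this package implements; the Shapley option
exists because it is the natural alternative reading with an efficiency
guarantee.

The empty coalition needs a convention, since singleton marginals
$v(\{d\}) - v(\varnothing)$ require it: $v(\varnothing)$ is the
no-information value of the metric — test prevalence for PR-AUC (its
random-guessing baseline), 0.5 for ROC-AUC, 0 for R², pseudo-R² and
IMV.

The coalition model defaults to `gbm_leafwise` (fast, missing-tolerant,
and the strongest default learner on these tables), and every $v(S)$ is
cached in a `coalition_ledger` keyed by coalition and seed, persisted
as JSON, so interrupted runs resume and repeated queries never refit
(asserted via a fit counter in the tests). Multi-seed runs average the
per-seed importances and report the across-seed standard error.
Exhaustive enumeration is capped at 12 domains; Monte-Carlo coalition
subsampling is deliberately out of scope since the target design has at
most seven.

## SHAP summaries

Attributions for the boosted-tree models are exact path-dependent
TreeSHAP — conditional expectations defined by the trees' own training
covers — computed by a compiled double-precision implementation in
`src/treeshap.cpp`. Two numerical details matter. First, boosters
evaluate in single precision; an attribution pass in single precision
carries an accumulation error of order $10^{-6}$ at realistic margins,
too coarse for a strict local-accuracy contract, so the package
recomputes attributions (and, via `predict_margin()`, margins) in
double precision from the extracted trees; local accuracy
$\big(\phi_0 + \sum_j \phi_{ij} = f(x_i)\big)$ then holds to
$10^{-12}$ or better, and agreement with the booster's own attribution
pass is at the single-precision noise floor. Second, split comparisons
are performed in `float32`, exactly as the booster performs them:
histogram-method thresholds coincide bitwise with `float32` feature
values, and a pure-double comparison misroutes a substantial share of
rows.

For non-tree models an interventional Shapley value against a
background sample is computed: exact coalition enumeration up to 12
features, permutation sampling above that (budget at least $2p + 2048$
model evaluations per row, fixed seed; local accuracy is exact by
telescoping for every sampled permutation), with a hard cap at 100
features.

Attributions are on the **log-odds margin scale**. On a probability
scale mean |SHAP| is bounded by 1, which cannot express the
attribution mass that age carries in strongly age-driven cohorts
(values well above 1 on the margin scale); the conventional stability
threshold of 0.1 for reporting a risk factor is therefore defined on
the margin scale, and `mean_abs_shap()` summaries carry scale metadata
so the threshold is never applied to probability-scale values. A
probability-scale option exists via the model-agnostic methods but is
not thresholded. Following the reporting convention for this analysis,
mean |SHAP| is computed over the full cohort (train plus test), and
individual-level attributions are never written to output files by the
pipeline — only aggregates leave the process.

Age stratification uses 5-year bins from 50 to 80 plus a single 80+
bin, matching how age-specific importance is conventionally reported
for these cohorts; bins with fewer than 30 individuals are flagged
unstable, and empty bins are kept with missing values.

## The synthetic-cohort generator

Each domain contributes a block of standardized Gaussian features with
equicorrelation $\rho$ (default 0.3), independent across domains — the
simplest structure in which within-domain redundancy makes coalition
marginals genuinely different from single-feature effects. Age is
uniform on its range and enters the linear predictor standardized, with
optional quadratic term; gender is Bernoulli (coded 1 = female,
matching the "female fraction" orientation of survey summary tables);
the demography domain always holds exactly age and gender plus optional
extra features. The outcome is Bernoulli(logistic($\alpha$ + linear
predictor)) with $\alpha$ calibrated by bisection so the expected
prevalence over the realized covariates is within $10^{-4}$ of target;
infeasible targets raise an error reporting the achievable range.
Missingness is applied completely at random to non-demographic features
only — the real surveys' missing-data mechanism is unknown, and MCAR
keeps recovery experiments interpretable. A `binary_fraction` flag
thresholds latent Gaussians to emulate binary survey items (the
death-generating process always uses the latent values, so planted
contributions stay analytic).

The analytic contribution of a domain to the variance of the linear
predictor is $\beta^\top \Sigma \beta = (1-\rho)\sum_j \beta_j^2 +
\rho\,(\sum_j \beta_j)^2$, plus, for demography,
$\beta_{\text{age}}^2 + \tfrac{4}{5}\beta_{\text{age}^2}^2 +
\beta_{\text{female}}^2\,p_f(1-p_f)$ (the 4/5 is the variance of the
squared standardized uniform age). `planted_domain_ranking()` orders
domains by these contributions — the ground truth for recovery tests —
and `domain_betas_for_contribution()` inverts the formula for
equal-beta blocks.

Two presets encode the package's study conditions:

* `recovery_spec()`: n = 10000, seven domains of sizes
  (3, 8, 10, 4, 6, 5, 8), prevalence 0.3, $\rho = 0.3$, 10%
  missingness, and planted variance contributions 9 (demography,
  split across a linear age effect, a gender effect, and one extra
  demographic feature), 4 (socioeconomic), and 0.90 / 0.65 / 0.45 /
  0.30 / 0.20 for the remaining five domains. The tail contributions
  are deliberately distinct rather than tied: a strict planted
  ordering is required for rank-correlation recovery measures to be
  well-defined, and all remain at or below 1 so the demography–
  socioeconomic dominance pattern is preserved.
* `ushape_spec()`: a quadratic age effect whose risk minimum (vertex)
  sits at age 67, with the uniform age distribution centered on the
  vertex (range 50–84) and curvature 1.0. Both choices follow from
  how SHAP works rather than convenience. The age attribution of an
  additive age effect measures deviation from its cohort mean, so the
  attribution profile dips where the effect *crosses its mean*; for a
  vertex-67 parabola under uniform ages 50–100 those crossings sit
  near ages 51 and 83 regardless of coefficient size, and no
  coefficient choice can make the 65–70 bin the low one. Centering
  the age distribution on the vertex places the attribution minimum
  at the vertex bin among the compared bins (50–55, 65–70, 80+).
  Moderate curvature matters too: strong curvature saturates the
  predicted probabilities at the age extremes, the log-loss gradient
  vanishes, and the fitted margins compress exactly where the planted
  deviations are largest, flattening the recovered profile.

What the generator does **not** emulate: real item distributions and
skip patterns, longitudinal wave structure, informative missingness,
cross-domain correlation, and harmonization artifacts. Passing
recovery tests therefore demonstrates that the pipeline measures what
it claims on data satisfying its assumptions, not that those
assumptions hold in any particular survey.

## Numerical choices and degenerate inputs

* All randomness flows from integer seeds carried in specs; stage
  seeds are derived deterministically from the replication seed, and
  no function mutates the caller's RNG state. Fits are single-threaded
  for bit-reproducibility.
* Probability clipping: $10^{-12}$ before logs in metrics; $10^{-7}$
  before logit when mapping generic model probabilities to margins.
* Ties: ROC-AUC counts ties one half; PR-AUC collapses tied scores
  into one threshold; mean-|SHAP| rankings and planted rankings break
  ties alphabetically.
* Degenerate inputs error early with named offenders: single-class
  training data, non-binary outcomes, unmapped features, empty
  coalitions, overlapping age bins, incomplete ledgers.
* Problem sizes in the test suite are chosen to exercise the exact
  study conditions where that is cheap (n = 10000 cohorts for
  calibration, null-signal, and recovery checks) and the rank-recovery
  experiment runs at its documented 3-seed smoke scale with the same
  allowed failure rate as the full 10-seed design.

## Limitations

The coalition analysis is exhaustive and retrains one model per
coalition per seed; its cost is $O(2^{|D|})$ fits and it is capped at
12 domains. Importances are metric- and model-relative: they quantify
contribution to a chosen test metric under a chosen learner, not causal
effect shares. Path-dependent TreeSHAP conditions on the trees'
training distribution, so correlated features share attribution in
model-specific ways (the duplicated-feature symmetry property holds for
the interventional methods, not the path-dependent one). The IMV
baseline convention and the SHAP variant used in the original analyses
are not fully documented there; both package defaults are stated above
and both alternatives are exposed as options.
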