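---
title: "Methods: automated model ranking and forward variable selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated model ranking and forward variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedure the package implements,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish.

## The decoding problem

The input is a numeric table of n samples by m features — in the
motivating application, gray-matter volumes of m parcellated brain
regions per subject — with a target (continuous or ordinal for
regression, e.g. coded age ranges; categorical for classification, e.g.
sex) and optional nuisance covariates such as total intracranial volume
(TIV). When m is comparable to or larger than n, both the choice of
estimator and the choice of feature subset dominate generalization
performance. The package automates both with a two-stage procedure.

## Stage 1: model ranking with nested tuning

For each model in the zoo, hyperparameters are tuned by k-fold
cross-validation (default k = 5) confined to a 70% training split; the
best configuration is refit on all training rows and evaluated once on
the untouched 30% test split. Models are ranked by test MSE (regression,
ascending) or test accuracy (classification, descending). The ranking
metric is deliberately the held-out metric, not the CV score: the
procedure's output claims generalization, so the sort key is the
generalization estimate.

Search strategy follows parameter-count: families with one or two tuned
parameters (the shrinkage-penalised linear models, kernel ridge, the
Gaussian process, elastic-net logistic regression, naive Bayes) are
tuned by exhaustive grid search; the many-parameter tree families and
the SGD learner use random search (default 50 draws per call,
configurable). Concrete grids are conventions, not fitted constants:
shrinkage strengths are 9 log-spaced points in 10^-4..10^4 (glmnet-style
penalties 10^-3..10), tree depths {2, 4, 8, 16, unlimited}, tree counts
{50, 100, 250, 500}. All grids live in one registry and can be
overridden per model by a configuration list or JSON file, which the
tests use extensively to trade tuning resolution for runtime without
touching the procedure.

Within one tuning call the CV folds are fixed across configurations, so
configuration comparisons are paired. A configuration that fails to fit
(e.g. a sigmoid kernel producing a singular system) is scored as
worst-possible and logged rather than aborting the search; only total
failure of every configuration is fatal, and a model that fails entirely
is dropped from the ranking with a logged error rather than killing the
stage.

### The estimator zoo

Eleven regression families: ridge (closed form on standardized
features), lasso, elastic net and multitask lasso (glmnet; the multitask
penalty with a single response reduces to the plain L1 problem, handled
by the multiresponse Gaussian family), least angle regression and
LassoLAR (an in-package LARS path implementation — LAR is tuned by the
nonzero-coefficient budget, LassoLAR by the L1 penalty, with coefficients
interpolated between path knots, which is exact because the path is
piecewise linear), kernel ridge regression (linear, Laplacian, Gaussian
and sigmoid kernels; the sigmoid kernel is indefinite, and configurations
where the linear system fails are scored worst by the failed-config
policy), Gaussian process regression (posterior mean; algebraically
kernel ridge with the noise variance as regularizer — the kernel and its
length scale are tuned), an SGD linear learner (squared or Huber loss,
L2/L1/elastic-net penalty via proximal shrinkage, constant or
inverse-scaling learning rate, 30 epochs), a CART decision tree and a
random forest. Seven classification families: CART tree (Gini or entropy
splits), random forest, extremely randomized trees (no bootstrap, random
thresholds), gradient boosting, extreme gradient boosting (adds a
parallel-tree count per stage: each stage grows a small bagged forest on
the stage gradients), elastic-net logistic regression and Gaussian naive
Bayes (the additive smoothing parameter scales the largest feature
variance added to every class-conditional variance — the continuous
analogue of Laplace/Lidstone count smoothing).

The tree engine is implemented in C++ in this package because the target
environment provides no tree-model packages. Stage trees in both
boosting variants are variance-criterion regression trees on gradients;
the "split quality" entry of the boosting parameter space is therefore a
single-option placeholder, documented here rather than silently absorbed.
Binary boosting uses Newton leaf updates on the binomial deviance;
multiclass problems are handled one-vs-rest with renormalized
probabilities. Forest importance is mean impurity decrease; an
out-of-bag permutation importance is available behind a flag.

## Stage 2: greedy forward selection

At iteration t with selected set S, a fresh 70/30 split is drawn
(seeded); every candidate f not in S is scored by the full nested
pipeline — tune by CV on the training rows restricted to S ∪ {f},
refit, score the test rows — and the best candidate is appended if it
beats the score of S alone on the *same* split by more than
`improvement_tol` (default 0, i.e. any strict improvement). The empty
set scores worst-possible, so the first feature is always accepted.
Selection stops at no improvement or at `n_selected_features`.

Design choices that were genuinely open:

- **Resplit granularity.** The split is redrawn once per iteration and
  shared by all of that iteration's candidates, so the candidate
  comparison is paired; the CV folds inside the shared split are also
  shared across candidates. Per-candidate resplitting would confound
  candidate quality with split luck.
- **Monotonicity vs resplitting.** With per-iteration resplitting,
  consecutive *recorded* scores live on different splits and need not
  decrease monotonically, though every accepted step strictly beats its
  same-split baseline (both numbers are recorded in the trace). In
  fixed-split mode (`resplit_each_iteration = FALSE`) the folds are
  fixed too, the baseline recomputation reproduces the previous step's
  score exactly, and the recorded sequence is strictly monotone; the
  greedy-equivalence and monotonicity properties are asserted in that
  mode.
- **Tie-breaking** is by lowest feature index, for determinism.
- **Parallelism.** Candidates are shuffled and dealt round-robin into
  worker queues (sizes differ by at most one). Every random quantity a
  candidate's evaluation consumes derives from (master seed, iteration,
  feature index) — never from worker identity — so the trace is
  byte-identical for any worker count. This is asserted as an acceptance
  property.
- **Retuning cadence.** `tune_every = 1` retunes hyperparameters for
  every candidate at every iteration (faithful to the procedure's
  description); `tune_every = k` reuses the last accepted step's tuned
  parameters between retunes as a cheaper mode.
- **Classification criterion** defaults to accuracy; AUC is available
  (`criterion = "auc"`) since the workflow reports both.

## Boruta counterpart

The all-relevant selector: per iteration, one permuted shadow copy of
each undecided feature is appended (permutation preserves the marginal
distribution, destroys the association with the target), a random
forest is fit on originals plus shadows, and an undecided feature
scores a *hit* if its importance exceeds the maximum shadow importance.
The shadow pool is padded to a minimum of five columns (extra
permutations cycling over the undecided features), as in canonical
implementations: with only one or two shadows the max-shadow bar
degenerates toward a coin flip exactly when the Bonferroni correction is
weakest, and lucky survivors of a pure-noise endgame would be falsely
accepted.
Accumulated hits are tested against Binomial(tested, 1/2) two-sided at
level alpha with Bonferroni correction over currently undecided
features; significant features are accepted or rejected, survivors at
`max_iter` (default 100) remain *tentative* — reported as their own
category, never forced. Importance z-scores against the shadow
distribution are recorded per iteration. Defaults: alpha 0.05, 100
trees, impurity importance.

## Covariate control

TIV-like nuisance covariates are removed by per-feature ordinary least
squares residualization with an intercept: coefficients are estimated on
the *training* rows only and applied to all rows, so the adjustment
cannot leak test information. Whether the original procedure
residualized, co-varied, or adjusted post hoc is not documented; OLS
residualization is standard practice in volumetric morphometry and is
the only leakage-safe variant of the three, which is why it was chosen.
The operation is idempotent for a fixed split and fatal on rank-deficient
covariate matrices.

## Synthetic data: what it emulates and what it does not

The generator produces equicorrelated Gaussian features (pairwise
correlation `rho`, default 0.3, mimicking the magnitude of inter-regional
volume correlations), a latent score that is a linear combination of the
first k features with coefficients of magnitude `effect` and alternating
sign plus Gaussian noise (`noise_sd`, default 1), and a TIV-like
covariate loading on every feature. Regression targets are the latent
score or its equal-frequency ordinal codes (the four-age-range
analogue); classification targets threshold the latent at its median
(binary, balanced by construction) or at quantiles. Ground truth
(informative names, coefficients) is attached for recovery tests.

Defaults (n = 300, m = 100, k = 5, effect = 2, rho = 0.3, noise 1) are
the acceptance conditions, chosen once: effect 2 against unit noise
makes each informative feature individually detectable but leaves
full-feature models visibly overfit at m ≈ n/1.5, which is the regime
the method targets.

Deliberately not emulated: realistic brain-atlas covariance (a single
equicorrelation parameter, not a spatial structure), non-Gaussian
marginals, site or batch effects, label noise. A green recovery test
therefore establishes that the greedy machinery finds planted linear
signal under correlated noise — not that it finds biologically correct
regions in real data, where signals are weaker, collinear and not
linear-additive.

## Numerical choices and degenerate inputs

- Losses (MSE/MAE) are minimized, accuracy/AUC maximized; orientation is
  centralized, and "worst possible" (±Inf) is the failure score and the
  empty-set baseline.
- Spearman correlation uses average ranks on ties and is reported as
  missing (with a warning) for constant vectors; precision/recall with a
  zero denominator are 0 with a warning; binary AUC is the Mann-Whitney
  statistic with ties counted half.
- The binary positive class is the lexicographically larger label unless
  overridden; multiclass metrics are macro-averaged, AUC one-vs-rest.
  Per-class recall is always emitted.
- Trees treat `max_depth = 0` as unlimited; split search respects
  minimum leaf sizes on both sides; tied feature values never produce a
  split point.
- All seeds derive from one master seed through a named-substream hash
  kept below 2^31, recorded in the CLI manifest.

## Known limitations

- Forward selection is greedy; it can lock in a locally optimal feature
  whose value is superseded by later combinations. No floating or
  backward steps are provided (out of scope by design).
- Per-candidate retuning makes cost grow as O(m · cap · configs · folds)
  model fits; the practical levers are the registry overrides, the
  feature cap, `tune_every`, and workers.
- The one-vs-rest reduction for multiclass boosting is an approximation
  to joint softmax boosting; for many classes a dedicated multinomial
  implementation would be preferable.
- The SGD learner is a fixed-epoch plain implementation intended as a
  faithful zoo member, not a tuned large-scale solver.
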