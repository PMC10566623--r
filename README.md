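# fvsdecode

Automated model ranking and greedy forward variable selection (FVS) for
decoding tabular, high-dimensional data — the typical case being a
region-of-interest (ROI) table from structural MRI: one row per subject,
one column per brain region's gray-matter volume, plus a target (age
range, sex, diagnosis, ...) and nuisance covariates such as total
intracranial volume (TIV).

## The problem and the method

When features far outnumber samples, most decoding models overfit, and
choosing *which* model and *which* features to use is itself a modeling
decision. `fvsdecode` automates both stages:

1. **Model ranking.** A fixed zoo of estimators — 11 regression families
   (ridge, lasso, kernel ridge, multitask lasso, LAR, LassoLAR, elastic
   net, SGD linear, decision tree, random forest, Gaussian process) and 7
   classification families (decision tree, random forest, gradient
   boosting, extreme gradient boosting, extremely randomized trees,
   elastic-net logistic regression, naive Bayes) — is tuned by grid or
   random search with k-fold cross-validation on a 70% training split and
   ranked by held-out performance on the remaining 30% (MSE for
   regression, accuracy for classification).

2. **Forward variable selection.** Given the chosen model, FVS greedily
   builds a feature set: at iteration *t* with selected set *S*, a fresh
   70/30 split is drawn; every candidate *f ∉ S* is scored by
   CV-tuning, refitting and evaluating the model on *S ∪ {f}*; the best
   candidate is appended if it improves the held-out score of *S* alone.
   Selection stops at no improvement or at the user's cap
   (`n_selected_features`). Candidate evaluation is distributed over
   worker queues; per-candidate seeds derive from (master seed,
   iteration, feature index) so the result is identical for any worker
   count.

A **Boruta** selector is included as the all-relevant counterpart: each
iteration appends one permuted "shadow" copy per undecided feature, fits
a random forest, counts hits against the maximum shadow importance, and
decides features by a Bonferroni-corrected binomial test.

Covariates of no interest are removed by per-feature OLS residualization
with coefficients estimated on training rows only (leakage-safe).

## Worked example

```r
library(fvsdecode)

# a synthetic ROI table: 300 subjects x 100 correlated regions, 5 of
# which carry signal, plus a TIV-like covariate
ds <- simulate_dataset(sim_config(n = 300, m = 100, k = 5, effect = 2,
                                  rho = 0.3, seed = 5))
split <- make_split(ds, split_config(seed = 1))
ds <- residualize_covariates(ds, split)

# stage 1: rank the zoo (subset + small grids shown for speed)
tab <- rank_models(ds, split, seed = 1,
                   models = c("ridge", "lassolar", "random_forest"),
                   config = list(random_forest = list(n_random_draws = 5)))
tab[, c("model", "mse", "spearman_rho")]
#>           model      mse spearman_rho
#> 1      lassolar 2.674002    0.9241882
#> 2         ridge 3.844169    0.8843808
#> 3 random_forest 9.575015    0.8428942

# stage 2: FVS with a fast linear model
trace <- forward_select(ds, fvs_config("ridge", n_selected_features = 10,
                                       master_seed = 1,
                                       param_space = list(alpha = c(0.01, 1, 100))))
selected_features(trace)
#>  [1] "roi_002" "roi_003" "roi_001" "roi_005" "roi_004" "roi_055" "roi_026"
#>  [8] "roi_081" "roi_015" "roi_079"
```

The first selections recover the five planted regions (`roi_001` ...
`roi_005`); the trace records, per iteration, the chosen feature, its
held-out score, the score of the set without it, and the tuned
hyperparameters.

Command-line equivalents:

```sh
Rscript -e 'fvsdecode::fvs_main()' simulate --n 300 --m 100 --k 5 --seed 5 \
    --task regression --out sim.csv
Rscript -e 'fvsdecode::fvs_main()' rank --input sim.csv --target target \
    --task regression --covariates TIV --seed 1 --out ranking.csv
Rscript -e 'fvsdecode::fvs_main()' fvs --input sim.csv --target target \
    --task regression --covariates TIV --model ridge \
    --n-selected-features 10 --seed 1 --out trace.csv
```

Every output directory gets a `manifest.json` recording the command,
full configuration, master seed, package version and input digest.

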