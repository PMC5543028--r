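---
title: "Benchmarking applicability-domain measures for two-class classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking applicability-domain measures for two-class classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbench)
```

## The problem

A classifier trained on molecular descriptors reports an *average* error
rate, but a medicinal chemist deciding which candidate to synthesize needs
to know how trustworthy the prediction is for *this particular* molecule.
The applicability domain (AD) formalizes that need: a per-object AD value,
oriented so that larger means less reliable, plus a threshold below which a
prediction is accepted. Two families of AD measures compete:

* **Novelty measures** use only the descriptors. They flag objects remote
  from the training density: the DA-index triple (kappa = distance to the
  kth nearest training neighbor, gamma = mean distance to the k nearest,
  delta = length of the mean difference vector to the k nearest), under
  Euclidean or Tanimoto distance, and one minus the mean cosine similarity
  to the k nearest neighbors. `k = 5` throughout.
* **Confidence measures** use the trained classifier and characterize the
  distance to its decision boundary: one minus the class-probability
  estimate of the predicted class; CLASS-LAG
  `min(|0 - yhat|, |1 - yhat|)` for regression-mode classifiers trained on
  0/1 targets; the ensemble standard deviation STD; PROB-STD, the normal
  tail area `pnorm(-|yhat - 0.5| / sigma)` beyond the 0.5 decision value;
  the vote fraction of an ensemble; and the normalized boosting margin
  `1 - |f|`.

This package implements the measures, the cross-validated benchmark that
ranks them, and the reject option that turns a measure plus threshold into
an error-rate/coverage trade-off. Because the benchmark's real descriptor
sets are external, a synthetic-data module generates datasets with the same
statistical structure, so that every stage is exercised end to end in code.

## The benchmarking construction

The central question for an AD measure is: *ranked by this measure, do the
errors concentrate among the "unreliable" objects?* The package evaluates
this with a signed-score ROC construction (`ad_ranking_score()`):

1. rank-normalize the AD values within the evaluated set (mean ranks for
   ties, mapped into (0,1)) and take the complement, giving a scale-free
   reliability `r` in (0,1);
2. sign it by the predicted class: `+r` for predicted class 1, `-r` for
   predicted class 2;
3. compute the ROC curve of this score with *true* class 1 as positive.

Confident correct predictions of class 1 then rank at the top, confident
correct predictions of class 2 at the bottom, and all errors drift toward
the center, so the AUC grows with the measure's ability to isolate errors.
Rank normalization makes the construction invariant under strictly
monotone transforms of the AD values, which is also why calibration steps
(e.g. Platt scaling of SVM decision values) cannot change any benchmark
outcome.

Two closed forms pin the construction down. For a classifier with
sensitivity *Sens* and specificity *Spec*,

* a random ordering of the errors yields
  `AUC_random = 0.5 (Sens + Spec)` — the median of the permutation null;
* the ideal ordering (every error ranked least reliable within its
  predicted class) yields `AUC_max = 1 - (1 - Sens)(1 - Spec)`.

The implementation is accepted only because it reproduces both forms
exactly; the test suite verifies `AUC_max` by brute-force pair counting on
2000-object constructions and the null median by permutation:

```{r closed-forms}
ps <- confusion_prediction_set(tp = 823, fn = 177, tn = 770, fp = 230)
roc_auc(ad_ranking_score(ps, ideal_ad(ps)), ps$true_class == 1)$auc
auc_max(0.823, 0.770)
```

Beyond ROC, two quantile curves support threshold setting: the cumulative
accuracy curve `CA(nu)` (accuracy of the predictions within the `nu`-th AD
quantile) and the predictiveness curve (local error rate per equal-count
AD bin, 10 bins by default). Significance of an AUC is assessed purely by
permutation: AD values are shuffled `B = 1000` times against fixed
predictions, `p = (1 + #[AUC_perm >= AUC_obs]) / (B + 1)`, and a measure
counts as significant when its AUC exceeds the null 95th percentile.

## The benchmark protocol

`benchmark_family()` / `run_benchmark()` chain the stages: continuous
descriptors are autoscaled on the *entire* matrix before cross-validation
— a mild information leak, but the convention this benchmark follows
deliberately; binary fingerprints stay raw — then stratified fivefold CV
produces pooled out-of-fold predictions, novelty scores are computed
fold-wise (each test fold against its own training partition, so no object
ever scores against itself), and each measure gets an AUC, a permutation
p-value, and finally a mean rank: per dataset, AUCs are rounded to two
decimals (half away from zero — differences beyond the second decimal are
noise at these sample sizes), ranked descending with mean ranks for ties,
and averaged across datasets.

When the minority class falls below 40% of a dataset, plain CV is replaced
by random-undersampling CV: inside each repetition (10 by default) every
training partition is undersampled to 1:1 balance, test partitions stay
untouched, and per-object probabilities are averaged over repetitions on
the probability scale before deriving the class and the AD values — the
same averaging convention the ensembles use.

## Classifier families and frozen hyperparameters

Six families are wrapped behind `classifier_spec()` / `fit_predict()`,
with deliberately frozen, library-default-leaning settings (the benchmark
design forgoes hyperparameter optimization entirely, trading a little
accuracy for zero model-selection bias — suboptimal models rarely change
the *ranking* of AD measures):

| family | implementation | settings | confidence measures |
|---|---|---|---|
| RF | randomForest | 500 trees; native regression defaults in regression mode | `p_hat_error`; regression: CLASS-LAG, STD, PROB-STD |
| NN | nnet, 5-member ensemble | 1 hidden layer of 5 units, decay 0.1, maxit 200; softmax (classification) or sigmoid output with squared error (regression) | as RF |
| SVM | e1071 (LIBSVM) | RBF, cost 1, gamma 1/p | Platt-calibrated `p_hat_error`; regression: CLASS-LAG |
| MB | in-package | bagging (10 bootstraps) of AdaBoost.M1 with 100 decision stumps | margin error `1 - |f|`, vote error `1 - nu` |
| kNN | in-package neighbor search | k = 5; Euclidean (continuous) or Tanimoto (binary) | `p_hat_error` |
| LDA | MASS | plain | `p_hat_error` |

Notes on choices that were genuinely open:

* **MB** is written in-package (weighted decision stumps, per-bag
  presorting, weight update `w <- w exp(-alpha y h)` with
  `alpha = 0.5 log((1 - eps)/eps)`, consistent with the probability
  transform `p = 1/(1 + exp(-2F))`). The per-bag normalized margin `f` is
  averaged into `f_bar`; the vote fraction counts the bagged boosted
  classifiers' sign votes.
* **SVM probabilities** are Platt-scaled on decision values from an
  internal fivefold CV of the training partition (resubstitution decision
  values would be optimistically separated). The predicted class is taken
  from the calibrated probability, which is the decision-value sign rule up
  to a shifted threshold and keeps `p_hat >= 0.5` structurally.
* **RF class probabilities** are per-tree vote averages; with fully grown
  trees the leaf class fractions are near 0/1, so the tree-probability
  average and the vote fraction coincide (the "coarse version"
  relationship, asserted in the tests).
* **k-NN** uses the package's own neighbor search (needed for the DA-index
  anyway) so that distance ties can be broken deterministically by training
  index; library k-NN routines break ties randomly.
* **Ties** at probability exactly 0.5 (or mean margin exactly 0) resolve
  to class 1, everywhere, for determinism.
* **PROB-STD at sigma = 0** takes its continuity limits: 0 off the
  boundary, 0.5 on it.
* **Delta under the Tanimoto metric**: Tanimoto induces no vector
  geometry, so the mean difference vector is still formed in raw
  descriptor space and measured with the Euclidean norm. Consequently the
  vector-norm chain `delta <= gamma <= kappa` is guaranteed (and tested)
  for the Euclidean metric only; under Tanimoto, `gamma <= kappa` holds.
* **Cosine on autoscaled data** can be negative, so the cosine AD value
  `1 - cos` lives in [0, 2] rather than [0, 1]; nothing downstream depends
  on the range, only on ranks.

## The synthetic data and what it does (not) show

`generate_gaussian_dataset()` draws two unit-variance Gaussian classes
whose means differ by `separation` on an evenly spread informative subset
of descriptors (symmetric about the origin, so autoscaling is
near-neutral; class sizes are `round(n * class_ratio)` with the remainder
in class 2). With one balanced informative descriptor the Bayes accuracy
is `pnorm(separation/2)` — the calibration handle for difficulty.
`generate_fingerprint_dataset()` draws independent per-bit Bernoulli
fingerprints with class-conditional on-probabilities.
`inject_novel_objects()` displaces a random fraction of objects by
`shift * sqrt(p)` in a random direction, keeping labels: remote but not
necessarily wrong, the setting that separates novelty from confidence.

The study conditions used by the analysis scripts and the acceptance
tests: five replicate datasets with `n = 400`, `p = 40`, class ratio
45/55, 10 informative descriptors at `separation = 0.5`, which puts the
pooled fivefold-CV AUC of LDA near 0.80 — the intermediate regime
(0.7–0.9) where AD measures differ most; `separation` 1.4 / 0.25 give the
easy (> 0.95) and hard (~0.55–0.65) regimes. These sizes keep the full
six-family benchmark within a few minutes on one CPU while leaving every
binomial error bar small enough for the rank comparisons.

What passing on this material shows: the measures, the CV plumbing, the
signed-score construction, the permutation test and the rank aggregation
all behave as designed, and the confidence-over-novelty ordering emerges
under controlled conditions. What it does not show: behavior under real
descriptor correlation structure, substructure-driven class boundaries,
activity cliffs, or heavy class overlap of real assay data — the
independent-Gaussian and independent-Bernoulli generators make no attempt
at chemistry. Conclusions about any particular real dataset still require
running the benchmark on it (`read_dataset_csv()` accepts any
descriptor CSV with a `label` column).

## The reject option

Three thresholding strategies are first-class, none is recommended by
default — they answer different operational questions:

* `threshold_by_training_quantile()`: exclude the x% most extreme
  training AD values (type-7 interpolation quantile);
* `threshold_by_local_error()`: largest predictiveness-curve prefix whose
  bins all stay at or below a local error limit;
* `threshold_by_accuracy_target()`: largest CA quantile still meeting a
  target overall accuracy.

`apply_reject()` reports coverage and the error rates inside/outside the
domain; the bookkeeping identity
`error_in * n_in + error_out * n_out = total errors` is exact and tested.

## Numerical conventions and limitations

Sample standard deviations use the n-1 denominator. Quantiles are R's
type 7. Equal-count predictiveness bins take the ceiling split
`ceiling(i/n * bins)`. Neighbor ties break by training index; rank ties by
mean rank. All generators and fits are pure functions of their seed
arguments (`with_seed` restores the caller's RNG state). Known
limitations: no conformal prediction, no density- or leverage-based AD
measures, no deep networks, no nested CV or hyperparameter search, and no
chemistry-aware data generation — all outside the benchmark's design. The
repository's `analysis/` scripts (01 simulate, 02 benchmark, 03 curves,
04 reject) are the narrative drivers over these functions and write their
tables under `results/`.
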