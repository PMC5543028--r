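# adbench

Applicability-domain (AD) measures for two-class classifiers on
cheminformatics-style tabular data, and the benchmarking machinery that
ranks them by how well they separate reliable from unreliable predictions.

QSAR-type classifiers report an average error rate, but decisions are made
molecule by molecule. An AD measure assigns each object a score, oriented
so that larger means less reliable, and a threshold on it defines the
applicability domain: predictions outside are rejected. Two kinds of
measure compete:

* **novelty measures** (labels never read): the DA-index
  — κ, the distance to the k-th nearest training neighbor; γ, the mean
  distance to the k nearest; δ, the length of the mean difference vector —
  under Euclidean or Tanimoto distance, and 1 − mean cosine similarity to
  the k nearest neighbors (k = 5 throughout);
* **confidence measures** (derived from the trained classifier): one minus
  the class-probability estimate of the predicted class, CLASS-LAG
  `min(|0 − ŷ|, |1 − ŷ|)` for regression-mode classifiers on 0/1 targets,
  the ensemble standard deviation (STD), PROB-STD
  `Φ(−|ŷ − 0.5|/σ̂)`, the ensemble vote fraction, and the normalized
  boosting margin error `1 − |f̄|`.

The benchmark ranks a measure by the ROC AUC of a **signed reliability
score**: AD values are rank-normalized into a reliability `r ∈ (0,1)`,
signed `+r` / `−r` by the predicted class, and the ROC is computed against
the true class. For a classifier with sensitivity *Sens* and specificity
*Spec* this construction has closed-form anchors

    AUC_random = 0.5 · (Sens + Spec)                (random error ordering)
    AUC_max    = 1 − (1 − Sens) · (1 − Spec)        (ideal error ordering)

which the implementation reproduces exactly. Significance is assessed by a
permutation test (AD values shuffled against fixed predictions), and
measures are aggregated across datasets by mean rank of their two-decimal
AUCs. Reject-option thresholds come in three flavors: training-set AD
quantile, local-error-rate limit (via predictiveness curves), and target
overall accuracy (via cumulative accuracy curves).

Six classifier families are wrapped with frozen hyperparameters: random
forests, ensembles of feedforward neural networks, RBF support vector
machines (classification probabilities via Platt scaling on internally
cross-validated decision values), bagged AdaBoost.M1 decision stumps,
k-nearest neighbors, and linear discriminant analysis; RF, NN and SVM run
in classification and in regression mode (0/1 targets, threshold 0.5).

A synthetic-data module generates Gaussian and fingerprint-like datasets
with tunable class imbalance and difficulty (easy / intermediate / hard
classifier regimes), plus injected remote "novel" objects, so the entire
pipeline runs without external data. Any descriptor CSV with a `label`
column can be benchmarked via `read_dataset_csv()`.

## Worked example

```r
library(adbench)

# a prediction set with sens = 0.823, spec = 0.770 and an ideal AD ordering
ps <- confusion_prediction_set(tp = 823, fn = 177, tn = 770, fp = 230)
roc_auc(ad_ranking_score(ps, ideal_ad(ps)), ps$true_class == 1)$auc
#> [1] 0.95929
auc_max(0.823, 0.770)        # the closed form it must reproduce
#> [1] 0.95929

# an intermediate-difficulty synthetic dataset, benchmarked with LDA
ds <- generate_gaussian_dataset(400, 40, class_ratio = 0.45,
                                separation = 0.5,
                                informative_fraction = 0.25, seed = 101,
                                name = "demo")
res <- benchmark_family(ds, "LDA", K = 5, B = 1000, seed = 1)
res[, c("measure", "category", "auc", "p_value", "significant")]
#>       measure   category       auc     p_value significant
#> 1 p_hat_error confidence 0.8357576 0.000999001        TRUE
#> 2   kappa_euc    novelty 0.7421465 0.977022977       FALSE
#> 3   gamma_euc    novelty 0.7467172 0.939060939       FALSE
#> 4   delta_euc    novelty 0.7466414 0.940059940       FALSE
#> 5      cos_ad    novelty 0.7835354 0.077922078       FALSE
```

The confidence measure (one minus the LDA posterior of the predicted
class) separates reliable from unreliable predictions clearly better than
any label-free novelty score: AUC 0.84 with the minimal permutation
p-value 1/(B+1), while the novelty AUCs (0.74–0.78) do not even clear the
random-ranking baseline `AUC_random = 0.5·(Sens + Spec)` of this
prediction set — the recurring fate of novelty measures in this
benchmark. The
`analysis/` scripts run this at full scale: `01_simulate_datasets.R`
writes the synthetic suite to `results/data/`, `02_benchmark_measures.R`
benchmarks all six families on five intermediate-difficulty datasets and
aggregates mean ranks, `03_curves.R` draws ROC / cumulative-accuracy /
predictiveness curves, and `04_reject_option.R` applies the three
thresholding strategies.

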