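#!/usr/bin/env Rscript
# Step 4: the reject option.
#
# Applies the three thresholding strategies to the random-forest confidence
# measure on an intermediate-difficulty dataset: a sweep of training-set AD
# quantiles (coverage vs retained error), a local-error-rate limit read off
# the predictiveness curve, and a target overall accuracy read off the
# cumulative accuracy curve.

library(adbench)

ds <- read_dataset_csv("results/data/intermediate_1.csv")
dss <- labeled_dataset(autoscale(ds$X)$X, ds$y, "continuous", name = ds$name)
n <- nrow(dss$X)
pred <- run_cv(dss, classifier_spec("RF"),
               kfold_split(n, 5, seed = 2, labels = dss$y))
ad <- 1 - pred$p_hat
cat(sprintf("overall error rate: %.3f\n", mean(!pred$correct)))

# strategy 1: training-quantile sweep
sweep <- do.call(rbind, lapply(c(0, 5, 10, 20, 30, 40), function(x) {
  r <- apply_reject(ad, threshold_by_training_quantile(ad, x), pred)
  data.frame(x_percent = x, coverage = r$coverage,
             error_inside = r$error_rate_inside,
             error_outside = r$error_rate_outside)
}))
print(sweep, row.names = FALSE, digits = 3)
write.csv(sweep, "results/reject_quantile_sweep.csv", row.names = FALSE)

# strategy 2: cap the local error rate at 0.30 (predictiveness lookup)
pc <- predictiveness_curve(pred, ad, bins = 10)
thr2 <- threshold_by_local_error(pc, 0.30)
r2 <- apply_reject(ad, thr2, pred)
cat(sprintf("local error <= 0.30: keep %.0f%% of the data, retained error %.3f\n",
            100 * r2$coverage, r2$error_rate_inside))

# strategy 3: require 90% expected accuracy among retained predictions
ca <- cumulative_accuracy_curve(pred, ad)
thr3 <- threshold_by_accuracy_target(ca, 0.90)
r3 <- apply_reject(ad, thr3, pred)
cat(sprintf("accuracy target 0.90: keep %.0f%% of the data, retained error %.3f\n",
            100 * r3$coverage, r3$error_rate_inside))
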