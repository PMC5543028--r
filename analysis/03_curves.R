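#!/usr/bin/env Rscript
# Step 3: performance curves for one (dataset, classifier) combination.
#
# For the first intermediate-difficulty dataset and a random forest, draws
# the three benchmarking curves for a good confidence measure (one minus
# the ensemble class-probability estimate) and a novelty measure (mean
# Euclidean 5-NN distance): ROC of the signed reliability score,
# cumulative accuracy over AD quantiles, and the predictiveness (local
# error rate) curve. Points go to CSV; a figure to results/figures/.

library(adbench)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
ds <- read_dataset_csv("results/data/intermediate_1.csv")
dss <- labeled_dataset(autoscale(ds$X)$X, ds$y, "continuous", name = ds$name)
n <- nrow(dss$X)
folds <- kfold_split(n, 5, seed = 2, labels = dss$y)

pred <- run_cv(dss, classifier_spec("RF"), folds)
cm <- confusion_metrics(pred)
cat(sprintf("RF: sens %.3f spec %.3f acc %.3f | AUC_random %.3f AUC_max %.3f\n",
            cm$sens, cm$spec, cm$acc, auc_random(cm$sens, cm$spec),
            auc_max(cm$sens, cm$spec)))

ad_conf <- 1 - pred$p_hat
nov <- data.frame(matrix(NA_real_, n, 0))
for (f in seq_len(folds$K)) {
  in_f <- folds$fold_id == f
  sc <- score_novelty(dss$X[!in_f, , drop = FALSE],
                      dss$X[in_f, , drop = FALSE], k = 5)
  if (ncol(nov) == 0) nov <- as.data.frame(
    matrix(NA_real_, n, ncol(sc), dimnames = list(NULL, names(sc))))
  nov[in_f, ] <- sc
}
ad_nov <- nov$gamma_euc

rows <- list()
for (m in c("p_hat_error", "gamma_euc")) {
  ad <- if (m == "p_hat_error") ad_conf else ad_nov
  roc <- roc_auc(ad_ranking_score(pred, ad), pred$true_class == 1L)
  ca <- cumulative_accuracy_curve(pred, ad)
  pc <- predictiveness_curve(pred, ad, bins = 10)
  cat(sprintf("  %-12s signed-score AUC %.3f | CA(0.5) %.3f | last-bin error %.2f\n",
              m, roc$auc, ca$ys[which.min(abs(ca$xs - 0.5))],
              pc$ys[length(pc$ys)]))
  rows[[m]] <- rbind(
    data.frame(measure = m, curve = "roc", x = roc$xs, y = roc$ys),
    data.frame(measure = m, curve = "cumulative_accuracy", x = ca$xs, y = ca$ys),
    data.frame(measure = m, curve = "predictiveness", x = pc$xs, y = pc$ys))
}
curves <- do.call(rbind, rows)
write.csv(curves, "results/curves_rf_intermediate.csv", row.names = FALSE)

png("results/figures/curves_rf_intermediate.png", 1200, 420, res = 110)
op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
cols <- c(p_hat_error = "firebrick", gamma_euc = "steelblue")
for (kind in c("roc", "cumulative_accuracy", "predictiveness")) {
  plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
       xlab = if (kind == "roc") "false positive rate" else "AD quantile",
       ylab = switch(kind, roc = "true positive rate",
                     cumulative_accuracy = "accuracy",
                     predictiveness = "local error rate"),
       main = kind)
  if (kind == "roc") abline(0, 1, lty = 3)
  for (m in names(cols)) {
    sub <- curves[curves$measure == m & curves$curve == kind, ]
    lines(sub$x, sub$y, col = cols[[m]], lwd = 2,
          type = if (kind == "predictiveness") "b" else "l")
  }
  legend("bottomright", legend = names(cols), col = unlist(cols), lwd = 2,
         bty = "n", cex = 0.9)
}
par(op)
dev.off()
cat("wrote results/curves_rf_intermediate.csv and the figure\n")
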