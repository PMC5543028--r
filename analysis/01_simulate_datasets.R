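#!/usr/bin/env Rscript
# Step 1: generate the synthetic benchmark suite.
#
# The suite emulates the statistical structure of molecular-descriptor
# benchmark sets: a few hundred to a few thousand objects, O(100)
# descriptors, class ratios from mild to strong imbalance, and three
# classifier-difficulty regimes (easy: pooled-CV AUC > 0.95, intermediate:
# 0.7-0.9, hard: ~0.55-0.65) controlled through the class-mean separation.
# A fingerprint-like binary dataset and a continuous dataset with injected
# remote ("novel") objects complete the suite. Everything is written as CSV
# under results/data/ for the later steps.

library(adbench)

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# five replicate intermediate-difficulty datasets: the conditions under
# which AD measures differ most, and the core material for step 2
for (s in 1:5) {
  ds <- generate_gaussian_dataset(400, 40, class_ratio = 0.45,
                                  separation = 0.5,
                                  informative_fraction = 0.25,
                                  seed = 100 + s,
                                  name = paste0("intermediate_", s))
  write_dataset_csv(ds, file.path(out_dir, paste0(ds$name, ".csv")))
}

# one dataset per difficulty regime (same n/p so only the separation moves)
regimes <- c(easy = 1.4, intermediate = 0.5, hard = 0.25)
for (r in names(regimes)) {
  ds <- generate_gaussian_dataset(400, 40, class_ratio = 0.45,
                                  separation = regimes[[r]],
                                  informative_fraction = 0.25,
                                  seed = 500, name = r)
  write_dataset_csv(ds, file.path(out_dir, paste0(r, ".csv")))
}

# fingerprint-like binary dataset (166 bits, 20 informative)
p_on1 <- c(rep(0.8, 20), rep(0.3, 146))
p_on2 <- c(rep(0.2, 20), rep(0.3, 146))
fp <- generate_fingerprint_dataset(1000, p_on1, p_on2, class_ratio = 0.38,
                                   seed = 600, name = "fingerprint")
write_dataset_csv(fp, file.path(out_dir, "fingerprint.csv"))

# continuous dataset with 10% remote objects for novelty-detection checks
nov <- inject_novel_objects(
  generate_gaussian_dataset(500, 40, class_ratio = 0.45, separation = 0.5,
                            informative_fraction = 0.25, seed = 700,
                            name = "with_novel"),
  fraction = 0.1, shift = 4, seed = 701)
write_dataset_csv(nov, file.path(out_dir, "with_novel.csv"))

# report the realized difficulty of the three regimes with a fast LDA CV
cat("difficulty check (pooled LDA AUC):\n")
for (r in names(regimes)) {
  ds <- read_dataset_csv(file.path(out_dir, paste0(r, ".csv")))
  dss <- labeled_dataset(autoscale(ds$X)$X, ds$y, "continuous", name = r)
  pred <- run_cv(dss, classifier_spec("LDA"),
                 kfold_split(nrow(dss$X), 5, seed = 1, labels = dss$y))
  cat(sprintf("  %-13s separation %.2f -> AUC %.3f, accuracy %.3f\n", r,
              regimes[[r]], roc_auc(pred$p1, pred$true_class == 1L)$auc,
              mean(pred$correct)))
}
cat("wrote", length(list.files(out_dir)), "datasets to", out_dir, "\n")
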