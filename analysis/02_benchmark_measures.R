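#!/usr/bin/env Rscript
# Step 2: the AD-measure benchmark.
#
# Every classifier family (RF, NN, SVM, MB, kNN, LDA) is cross-validated on
# the five intermediate-difficulty datasets from step 1; every applicable
# AD measure -- label-free novelty scores and classifier-derived confidence
# scores -- is evaluated by its signed-score ROC AUC with a 1000-permutation
# significance test; AUCs are rounded to two decimals, ranked per dataset
# and averaged into a mean rank per (family, measure). The key question:
# does any novelty measure ever outperform a confidence measure?

library(adbench)

dir.create("results", showWarnings = FALSE)
paths <- sprintf("results/data/intermediate_%d.csv", 1:5)
if (!all(file.exists(paths)))
  stop("run analysis/01_simulate_datasets.R first")
datasets <- lapply(paths, read_dataset_csv)

t0 <- Sys.time()
res <- run_benchmark(datasets, families = c("RF", "NN", "SVM", "MB",
                                            "kNN", "LDA"),
                     K = 5, B = 1000, seed = 1)
cat(sprintf("benchmark finished in %.1f min\n",
            as.numeric(Sys.time() - t0, units = "mins")))

write.csv(res, "results/benchmark_auc.csv", row.names = FALSE)
summ <- summarize_benchmark(res)
write.csv(summ, "results/benchmark_summary.csv", row.names = FALSE)
writeLines(format_benchmark_table(res), "results/benchmark_report.txt")

cat("\n", paste(format_benchmark_table(res), collapse = "\n"), "\n\n", sep = "")

# headline comparison: best confidence vs best novelty rank per family
cat("confidence vs novelty (mean ranks):\n")
flip <- FALSE
for (fam in unique(summ$family)) {
  sub <- summ[summ$family == fam, ]
  best_conf <- min(sub$mean_rank[sub$category == "confidence"])
  best_nov <- min(sub$mean_rank[sub$category == "novelty"])
  worst_conf <- max(sub$mean_rank[sub$category == "confidence"])
  cat(sprintf("  %-4s best confidence %.2f | best novelty %.2f%s\n", fam,
              best_conf, best_nov,
              if (worst_conf < best_nov) "  (every confidence measure ranks above every novelty measure)" else ""))
  if (best_nov < worst_conf) flip <- TRUE
}
cat(if (flip) "NOTE: at least one novelty measure beat a confidence measure\n"
    else "no novelty measure outperforms any confidence measure here\n")
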