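#' Benchmark every AD measure of one classifier family on one dataset
#'
#' Runs the full per-dataset benchmarking protocol for a family:
#' continuous descriptors are autoscaled on the entire matrix before
#' cross-validation (the convention of the benchmark this package
#' implements; binary fingerprints stay raw), stratified K-fold CV produces
#' pooled out-of-fold predictions (random-undersampling CV when the
#' minority class is below the `rus_threshold`), the label-free novelty
#' scores are computed fold-wise (each test fold scored against its own
#' training partition), and every applicable AD measure is evaluated by its
#' signed-score ROC AUC plus a permutation significance test.
#'
#' Regression-capable families (RF, NN, SVM) are additionally run in
#' regression mode; their regression-derived measures are evaluated against
#' the regression-mode predictions, all novelty measures against the
#' classification-mode predictions.
#'
#' @param ds a [labeled_dataset()].
#' @param family classifier family name (see [classifier_spec()]).
#' @param K fold count (default 5).
#' @param B permutation count for significance (default 1000; `0` skips
#'   the permutation test).
#' @param seed integer seed driving folds, fits and permutations.
#' @param k_novelty neighbor count for the novelty measures (default 5).
#' @param rus `"auto"` (undersample when the minority class is below
#'   `rus_threshold`), `TRUE` or `FALSE`.
#' @param rus_threshold minority-fraction cutoff for automatic RUS
#'   (default 0.4).
#' @param spec_args named list of hyperparameter overrides passed to
#'   [classifier_spec()].
#' @return data.frame with one row per measure: `dataset`, `family`,
#'   `measure`, `category`, `auc`, `p_value`, `significant`, plus the
#'   prediction sets as attributes.
#' @export
benchmark_family <- function(ds, family, K = 5, B = 1000, seed = 1,
                             k_novelty = 5, rus = "auto",
                             rus_threshold = 0.4, spec_args = list()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (ds$feature_kind == "continuous")
    ds <- labeled_dataset(autoscale(ds$X)$X, ds$y, "continuous",
                          novel_flag = ds$novel_flag, name = ds$name)
  n <- nrow(ds$X)
  use_rus <- if (identical(rus, "auto"))
    min(table(ds$y)) / n < rus_threshold else isTRUE(rus)
  folds <- kfold_split(n, K, seed = seed, labels = ds$y)

  cv_for <- function(mode) {
    spec <- do.call(classifier_spec,
                    c(list(family = family, mode = mode, seed = seed),
                      spec_args))
    pred <- if (use_rus) rus_cv(ds, spec, K = K, seed = seed)
            else run_cv(ds, spec, folds)
    list(spec = spec, pred = pred)
  }

  cls <- cv_for("classification")
  measures <- list()   # each: list(values, category, pred)
  conf_c <- collect_confidence(cls$pred, cls$spec)
  for (m in names(conf_c))
    measures[[m]] <- list(values = conf_c[[m]], category = "confidence",
                          pred = cls$pred)
  if (family %in% c("RF", "NN", "SVM")) {
    reg <- cv_for("regression")
    conf_r <- collect_confidence(reg$pred, reg$spec)
    for (m in names(conf_r))
      measures[[paste0(m, "_reg")]] <-
        list(values = conf_r[[m]], category = "confidence", pred = reg$pred)
  }

  # fold-wise novelty scores: each test fold against its training partition
  nov <- NULL
  for (f in seq_len(folds$K)) {
    in_f <- folds$fold_id == f
    sc <- score_novelty(ds$X[!in_f, , drop = FALSE],
                        ds$X[in_f, , drop = FALSE], k = k_novelty)
    if (is.null(nov)) {
      nov <- as.data.frame(matrix(NA_real_, n, ncol(sc),
                                  dimnames = list(NULL, names(sc))))
    }
    nov[in_f, ] <- sc
  }
  for (m in names(nov))
    measures[[m]] <- list(values = nov[[m]], category = "novelty",
                          pred = cls$pred)

  rows <- lapply(names(measures), function(m) {
    x <- measures[[m]]
    if (B > 0) {
      pt <- permutation_test_auc(x$pred, x$values, B = B,
                                 seed = seed + 7919L)
      data.frame(dataset = ds$name, family = family, measure = m,
                 category = x$category, auc = pt$auc_obs,
                 p_value = pt$p_value, significant = pt$significant)
    } else {
      sc <- ad_ranking_score(x$pred, x$values)
      data.frame(dataset = ds$name, family = family, measure = m,
                 category = x$category,
                 auc = roc_auc(sc, x$pred$true_class == 1L)$auc,
                 p_value = NA_real_, significant = NA)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- lapply(measures, `[[`, "pred")
  out
}

#' Run the AD-measure benchmark over datasets and classifier families
#'
#' The top-level pipeline: [benchmark_family()] for every (dataset, family)
#' pair, stacked into one long table -- the raw material for
#' [summarize_benchmark()].
#'
#' @param datasets list of [labeled_dataset()]s (names taken from each
#'   dataset's `name`).
#' @param families character vector of family names.
#' @inheritParams benchmark_family
#' @return long data.frame with columns `dataset`, `family`, `measure`,
#'   `category`, `auc`, `p_value`, `significant`.
#' @export
run_benchmark <- function(datasets, families = c("RF", "NN", "SVM", "MB",
                                                 "kNN", "LDA"),
                          K = 5, B = 1000, seed = 1, k_novelty = 5,
                          rus = "auto", spec_args = list()) {
  rows <- list()
  for (i in seq_along(datasets)) {
    for (fam in families) {
      rows[[length(rows) + 1L]] <-
        benchmark_family(datasets[[i]], fam, K = K, B = B,
                         seed = seed + i, k_novelty = k_novelty, rus = rus,
                         spec_args = spec_args)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) { attributes(r)$predictions <- NULL; r }))
  rownames(out) <- NULL
  out
}

#' Aggregate a benchmark run into per-family mean ranks
#'
#' For each classifier family, builds the measures x datasets AUC matrix,
#' applies [rank_measures()] (two-decimal rounding, mean rank over
#' datasets) and counts per measure the datasets with a significant
#' permutation test.
#'
#' @param results long data.frame from [run_benchmark()].
#' @return data.frame with `family`, `measure`, `category`, `mean_rank`,
#'   `mean_auc`, `n_significant`, sorted by family and mean rank.
#' @export
summarize_benchmark <- function(results) {
  out <- list()
  for (fam in unique(results$family)) {
    sub <- results[results$family == fam, , drop = FALSE]
    auc_tab <- tapply(sub$auc, list(sub$measure, sub$dataset), identity)
    rk <- rank_measures(auc_tab)
    cat_map <- tapply(sub$category, sub$measure, `[`, 1L)
    nsig <- tapply(sub$significant, sub$measure, function(s)
      if (all(is.na(s))) NA_integer_ else sum(s, na.rm = TRUE))
    mauc <- tapply(sub$auc, sub$measure, mean)
    out[[fam]] <- data.frame(family = fam, measure = rk$measure,
                             category = as.character(cat_map[rk$measure]),
                             mean_rank = rk$mean_rank,
                             mean_auc = as.numeric(mauc[rk$measure]),
                             n_significant = as.integer(nsig[rk$measure]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Format a benchmark summary as a text report
#'
#' Measure rows grouped by classifier family, one dataset per column
#' (two-decimal AUCs), followed by the mean-rank and significance-count
#' columns.
#'
#' @param results long data.frame from [run_benchmark()].
#' @return character vector of report lines (printable via `cat`).
#' @export
format_benchmark_table <- function(results) {
  summary <- summarize_benchmark(results)
  datasets <- unique(results$dataset)
  lines <- c(sprintf("%-16s %s %9s %7s", "measure",
                     paste(sprintf("%8s", substr(datasets, 1, 8)),
                           collapse = " "),
                     "mean_rank", "#signif"))
  for (fam in unique(summary$family)) {
    lines <- c(lines, sprintf("-- %s --", fam))
    sub <- summary[summary$family == fam, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      m <- sub$measure[i]
      aucs <- vapply(datasets, function(d) {
        results$auc[results$family == fam & results$measure == m &
                      results$dataset == d][1]
      }, numeric(1))
      lines <- c(lines, sprintf("%-16s %s %9.2f %7s", m,
                                paste(sprintf("%8.2f", round_half_up(aucs)),
                                      collapse = " "),
                                sub$mean_rank[i],
                                ifelse(is.na(sub$n_significant[i]), "-",
                                       sub$n_significant[i])))
    }
  }
  lines
}
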