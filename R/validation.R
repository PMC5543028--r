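#' Random (optionally stratified) K-fold partition
#'
#' Fold sizes differ by at most one. When `labels` are supplied the split is
#' stratified: each class is partitioned separately so per-fold class ratios
#' match the global ratio within rounding.
#'
#' @param n object count.
#' @param K fold count (>= 2).
#' @param seed integer RNG seed.
#' @param labels optional class labels for stratification.
#' @return list with `fold_id` (length-n integer vector in `1..K`), `K`,
#'   `seed`.
#' @export
kfold_split <- function(n, K = 5, seed = 1, labels = NULL) {
  if (K < 2) stop("K must be at least 2")
  if (n < K) stop("fewer objects than folds")
  fold_id <- integer(n)
  with_seed(seed, {
    if (is.null(labels)) {
      fold_id <- sample(rep_len(seq_len(K), n))
    } else {
      stopifnot(length(labels) == n)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold_id[idx] <- sample(rep_len(seq_len(K), length(idx)))
      }
    }
  })
  list(fold_id = fold_id, K = as.integer(K), seed = as.integer(seed))
}

#' Write / read a fold assignment as a two-column CSV
#'
#' Columns `object` (1-based index) and `fold`, so published CV splits can
#' be imported.
#'
#' @param folds a fold assignment as from [kfold_split()].
#' @param path CSV path.
#' @return `read_folds_csv` returns a fold-assignment list.
#' @export
write_folds_csv <- function(folds, path) {
  utils::write.csv(data.frame(object = seq_along(folds$fold_id),
                              fold = folds$fold_id),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds_csv
#' @export
read_folds_csv <- function(path) {
  df <- utils::read.csv(path)
  fold_id <- integer(nrow(df))
  fold_id[df$object] <- df$fold
  list(fold_id = fold_id, K = max(df$fold), seed = NA_integer_)
}

# combine per-fold prediction_sets into one pooled set (original order)
pool_predictions <- function(pred_list, fold_idx_list, n, true_class) {
  fields <- c("predicted_class", "p1", "p_hat", "p_hat_error", "y_hat",
              "decision_value", "sigma_hat", "f_bar", "nu_hat")
  pooled <- list()
  for (f in fields) {
    if (is.null(pred_list[[1]][[f]])) next
    v <- rep(NA_real_, n)
    for (i in seq_along(pred_list)) v[fold_idx_list[[i]]] <- pred_list[[i]][[f]]
    pooled[[f]] <- v
  }
  if (!is.null(pred_list[[1]]$member_outputs)) {
    m <- ncol(pred_list[[1]]$member_outputs)
    mo <- matrix(NA_real_, n, m)
    for (i in seq_along(pred_list))
      mo[fold_idx_list[[i]], ] <- pred_list[[i]]$member_outputs
    pooled$member_outputs <- mo
  }
  pooled$predicted_class <- as.integer(pooled$predicted_class)
  pooled$true_class <- as.integer(true_class)
  pooled$correct <- pooled$predicted_class == pooled$true_class
  structure(pooled, class = "prediction_set")
}

#' Cross-validated out-of-fold predictions
#'
#' Fits the classifier on each training partition and predicts the held-out
#' fold, so every object is predicted exactly once by a model that never saw
#' it. All confidence fields the family supports are pooled in original
#' object order; `true_class` and `correct` are filled in.
#'
#' @param ds a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @param folds a fold assignment from [kfold_split()] matching `ds`.
#' @return a pooled `prediction_set` of length `nrow(ds$X)`.
#' @export
run_cv <- function(ds, spec, folds) {
  stopifnot(inherits(ds, "labeled_dataset"),
            length(folds$fold_id) == nrow(ds$X))
  preds <- vector("list", folds$K)
  idxs <- vector("list", folds$K)
  for (f in seq_len(folds$K)) {
    in_f <- folds$fold_id == f
    train <- labeled_dataset(ds$X[!in_f, , drop = FALSE], ds$y[!in_f],
                             ds$feature_kind, name = ds$name)
    if (length(unique(train$y)) < 2)
      stop("degenerate fold: a training partition lost a class")
    spec_f <- spec
    spec_f$seed <- spec$seed + f
    preds[[f]] <- fit_predict(spec_f, train, ds$X[in_f, , drop = FALSE])
    idxs[[f]] <- which(in_f)
  }
  pool_predictions(preds, idxs, nrow(ds$X), ds$y)
}

#' Random-undersampling cross-validation for imbalanced data
#'
#' Like [run_cv()], but inside each repetition every training partition is
#' randomly undersampled to a 1:1 class balance before fitting; test
#' partitions are left untouched so the pooled metrics stay unbiased.
#' Per-object class-1 probabilities are averaged over the repeats on the
#' probability scale, and the predicted class (and the derived fields) come
#' from the averaged probability.
#'
#' @param ds a [labeled_dataset()]; intended for minority fractions below
#'   0.4 (a warning is emitted otherwise).
#' @param spec a [classifier_spec()].
#' @param K fold count.
#' @param repeats number of undersampling repetitions (default 10).
#' @param seed integer RNG seed for folds and undersampling.
#' @return a pooled `prediction_set` with fields averaged over repeats.
#' @export
rus_cv <- function(ds, spec, K = 5, repeats = 10, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- nrow(ds$X)
  min_frac <- min(table(ds$y)) / n
  if (min_frac >= 0.4)
    warning("minority class is >= 40% of the data; plain CV is adequate")
  acc <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- kfold_split(n, K, seed = seed + r - 1L, labels = ds$y)
    preds <- vector("list", K)
    idxs <- vector("list", K)
    for (f in seq_len(K)) {
      in_f <- folds$fold_id == f
      tr_idx <- which(!in_f)
      i1 <- tr_idx[ds$y[tr_idx] == 1L]
      i2 <- tr_idx[ds$y[tr_idx] == 2L]
      m <- min(length(i1), length(i2))
      if (m < 2) stop("undersampled training fold has fewer than 2 per class")
      keep <- with_seed(seed * 1000L + r * 10L + f, {
        c(if (length(i1) > m) sample(i1, m) else i1,
          if (length(i2) > m) sample(i2, m) else i2)
      })
      train <- labeled_dataset(ds$X[keep, , drop = FALSE], ds$y[keep],
                               ds$feature_kind, name = ds$name)
      spec_f <- spec
      spec_f$seed <- spec$seed + r * K + f
      preds[[f]] <- fit_predict(spec_f, train, ds$X[in_f, , drop = FALSE])
      idxs[[f]] <- which(in_f)
    }
    acc[[r]] <- pool_predictions(preds, idxs, n, ds$y)
  }
  avg <- function(field) {
    if (is.null(acc[[1]][[field]])) return(NULL)
    Reduce(`+`, lapply(acc, `[[`, field)) / repeats
  }
  p1 <- avg("p1")
  out <- prediction_set(class_from_score(p1), p1, y_hat = avg("y_hat"),
                        sigma_hat = avg("sigma_hat"), f_bar = avg("f_bar"),
                        nu_hat = avg("nu_hat"), true_class = ds$y)
  out
}

#' Confusion-matrix metrics of a prediction set
#'
#' Class 1 is the positive class. Sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, accuracy `(tp+tn)/n`. If a true class is absent the
#' corresponding rate is `NaN` and a warning is emitted.
#'
#' @param pred a `prediction_set` with `true_class` present.
#' @return list with `sens`, `spec`, `acc`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(pred) {
  stopifnot(inherits(pred, "prediction_set"), !is.null(pred$true_class))
  tp <- sum(pred$predicted_class == 1L & pred$true_class == 1L)
  fn <- sum(pred$predicted_class == 2L & pred$true_class == 1L)
  tn <- sum(pred$predicted_class == 2L & pred$true_class == 2L)
  fp <- sum(pred$predicted_class == 1L & pred$true_class == 2L)
  if (tp + fn == 0 || tn + fp == 0)
    warning("one true class is absent; sensitivity or specificity undefined")
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       acc = (tp + tn) / length(pred$true_class),
       tp = tp, fp = fp, tn = tn, fn = fn)
}
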