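#' Signed reliability score for benchmarking an AD measure with ROC curves
#'
#' Converts per-object AD values into a single ranking whose ROC curve
#' (with true class 1 as positive) measures how well the AD measure
#' separates reliable from unreliable predictions. The AD values are first
#' rank-normalized within the evaluated set (mean rank for ties, mapped to
#' (0,1)), giving a scale-free reliability `r_i = 1 - (rank_i - 0.5)/n`;
#' the signed score is `+r_i` for objects predicted as class 1 and `-r_i`
#' for objects predicted as class 2. Confidently predicted class-1 objects
#' thus rank at the top, confidently predicted class-2 objects at the
#' bottom, and unreliable predictions of either class fall toward the
#' center -- exactly the geometry that yields the closed-form bounds
#' [auc_random()] (random ordering of the errors) and [auc_max()] (errors
#' ranked least reliable within each predicted class).
#'
#' @param pred a `prediction_set`.
#' @param ad numeric vector of AD values (larger = less reliable), one per
#'   object.
#' @return numeric vector of signed scores in `(-1, 1)`.
#' @export
ad_ranking_score <- function(pred, ad) {
  stopifnot(inherits(pred, "prediction_set"),
            length(ad) == length(pred$predicted_class))
  n <- length(ad)
  r <- 1 - (rank(ad, ties.method = "average") - 0.5) / n
  ifelse(pred$predicted_class == 1L, r, -r)
}

#' ROC curve and AUC of a score against a positive-class indicator
#'
#' Standard ROC by descending score. Tied scores form a single step
#' (diagonal segment), so the trapezoidal AUC equals the Mann-Whitney
#' pair-counting statistic with ties counted 1/2.
#'
#' @param scores numeric score vector (larger = more class-1-like).
#' @param positive logical vector, `TRUE` for true class 1.
#' @return list of class `curve_data` with `kind = "roc"`, `xs` (FPR),
#'   `ys` (TPR), `auc`, `n`.
#' @export
roc_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC undefined: one class is absent")
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(positive[o])
  fp <- cumsum(!positive[o])
  last <- !duplicated(scores[o], fromLast = TRUE)  # one point per threshold
  xs <- c(0, fp[last] / n_neg)
  ys <- c(0, tp[last] / n_pos)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  structure(list(kind = "roc", xs = xs, ys = ys, auc = auc,
                 n = length(scores)),
            class = "curve_data")
}

#' @export
print.curve_data <- function(x, ...) {
  cat(sprintf("curve_data (%s), %d points over %d objects", x$kind,
              length(x$xs), x$n))
  if (!is.null(x$auc)) cat(sprintf(", AUC = %.4f", x$auc))
  cat("\n")
  invisible(x)
}

# fast AUC used in the permutation loop (Mann-Whitney rank form, mid-ranks)
auc_stat <- function(scores, positive, n_pos, n_neg) {
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Closed-form AUC of a randomly ranked set of prediction errors
#'
#' When the AD values carry no information about correctness, the median of
#' the permutation distribution of the signed-score ROC AUC is
#' `0.5 * (sens + spec)`.
#'
#' @param sens,spec sensitivity and specificity in `[0, 1]`.
#' @return scalar AUC.
#' @export
auc_random <- function(sens, spec) {
  if (any(c(sens, spec) < 0) || any(c(sens, spec) > 1))
    stop("sens and spec must lie in [0, 1]")
  0.5 * (sens + spec)
}

#' Closed-form maximum obtainable signed-score ROC AUC
#'
#' With an ideal AD measure (all errors ranked least reliable within each
#' predicted class) the signed-score ROC AUC equals
#' `1 - (1 - sens) * (1 - spec)`.
#'
#' @inheritParams auc_random
#' @return scalar AUC.
#' @export
auc_max <- function(sens, spec) {
  if (any(c(sens, spec) < 0) || any(c(sens, spec) > 1))
    stop("sens and spec must lie in [0, 1]")
  1 - (1 - sens) * (1 - spec)
}

#' Cumulative accuracy curve
#'
#' `CA(nu)` is the accuracy of the predictions whose AD value lies at or
#' below the `nu`-th empirical quantile of the AD values; `CA(1)` is the
#' overall accuracy. Reading the curve right to left shows the accuracy
#' gain bought by rejecting increasingly large AD values.
#'
#' @param pred a `prediction_set` with `correct` present.
#' @param ad numeric AD values (larger = less reliable).
#' @param quantiles evaluation grid in (0, 1].
#' @return `curve_data` with `kind = "cumulative_accuracy"`, `xs` =
#'   quantiles, `ys` = accuracies, and attribute `ad_cutoffs` (the AD value
#'   at each quantile).
#' @export
cumulative_accuracy_curve <- function(pred, ad,
                                      quantiles = seq(0.05, 1, by = 0.05)) {
  stopifnot(inherits(pred, "prediction_set"), !is.null(pred$correct),
            length(ad) == length(pred$correct))
  cuts <- stats::quantile(ad, quantiles, names = FALSE)
  ys <- vapply(cuts, function(q) mean(pred$correct[ad <= q]), numeric(1))
  out <- structure(list(kind = "cumulative_accuracy", xs = quantiles,
                        ys = ys, auc = NULL, n = length(ad)),
                   class = "curve_data")
  attr(out, "ad_cutoffs") <- cuts
  out
}

#' Predictiveness curve (local error rate per AD quantile)
#'
#' Objects are sorted by AD value (ties by original index) and partitioned
#' into `bins` equal-count bins; the per-bin error rate is plotted at the
#' bin-center quantile. A well-working AD measure shows a sharp rise of the
#' local error rate in the last bins.
#'
#' @param pred a `prediction_set` with `correct` present.
#' @param ad numeric AD values.
#' @param bins number of equal-count bins (default 10).
#' @return `curve_data` with `kind = "predictiveness"`, `xs` = bin-center
#'   quantiles, `ys` = per-bin error rates, and attribute `ad_cutoffs`
#'   (largest AD value in each bin).
#' @export
predictiveness_curve <- function(pred, ad, bins = 10) {
  stopifnot(inherits(pred, "prediction_set"), !is.null(pred$correct),
            length(ad) == length(pred$correct))
  n <- length(ad)
  if (bins > n) stop("more bins than objects")
  o <- order(ad, seq_len(n))
  bin <- ceiling(seq_len(n) / n * bins)
  err <- tapply(!pred$correct[o], bin, mean)
  cutoff <- tapply(ad[o], bin, max)
  out <- structure(list(kind = "predictiveness",
                        xs = (seq_len(bins) - 0.5) / bins,
                        ys = as.numeric(err), auc = NULL, n = n),
                   class = "curve_data")
  attr(out, "ad_cutoffs") <- as.numeric(cutoff)
  out
}

#' Permutation test of a signed-score ROC AUC
#'
#' Permutes the AD values across objects `B` times with predictions and
#' correctness fixed, recomputing the signed-score AUC each time. The
#' p-value is `(1 + #{AUC_perm >= AUC_obs}) / (B + 1)`; the measure is
#' flagged significant when the observed AUC exceeds the 95th percentile of
#' the null distribution. The null median approximates [auc_random()] of
#' the prediction set.
#'
#' @param pred a `prediction_set` with `true_class`.
#' @param ad numeric AD values.
#' @param B permutation count (>= 99; default 1000).
#' @param seed integer RNG seed.
#' @param alpha significance level for the percentile flag.
#' @return list with `auc_obs`, `p_value`, `significant`, `null_median`,
#'   `null_q95`, `B`.
#' @export
permutation_test_auc <- function(pred, ad, B = 1000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(pred, "prediction_set"), !is.null(pred$true_class))
  if (B < 99) stop("use at least 99 permutations")
  n <- length(ad)
  positive <- pred$true_class == 1L
  n_pos <- sum(positive)
  n_neg <- n - n_pos
  sgn <- ifelse(pred$predicted_class == 1L, 1, -1)
  r0 <- 1 - (rank(ad, ties.method = "average") - 0.5) / n
  auc_obs <- auc_stat(sgn * r0, positive, n_pos, n_neg)
  null_auc <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      auc_stat(sgn * r0[sample.int(n)], positive, n_pos, n_neg)
    }, numeric(1))
  })
  q95 <- stats::quantile(null_auc, 1 - alpha, names = FALSE)
  list(auc_obs = auc_obs,
       p_value = (1 + sum(null_auc >= auc_obs)) / (B + 1),
       significant = auc_obs > q95,
       null_median = stats::median(null_auc),
       null_q95 = q95, B = B)
}

#' Round half away from zero
#'
#' Decimal rounding with halves moving away from zero, the convention of
#' printed benchmark tables (e.g. 0.7965 -> 0.797 at three digits, where
#' banker's rounding would print 0.796). A tiny relative guard absorbs
#' binary floating-point representation error of decimal halves.
#'
#' @param x numeric vector.
#' @param digits decimal digits to keep.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5 + 1e-9) / pow
}

#' Rank AD measures across datasets from an AUC table
#'
#' Implements the benchmark-table aggregation: per dataset, AUC values are
#' rounded to two decimals (half away from zero), measures are ranked by
#' rounded AUC descending (rank 1 = best) with ties receiving the mean
#' rank, and ranks are averaged across datasets.
#'
#' @param auc_table numeric matrix, measures x datasets (dimnames used in
#'   the output), no missing cells.
#' @param round_digits decimals to round to before ranking (default 2;
#'   `Inf` ranks unrounded values).
#' @return data.frame with `measure`, `mean_rank`, sorted best first.
#' @export
rank_measures <- function(auc_table, round_digits = 2) {
  auc_table <- as.matrix(auc_table)
  if (anyNA(auc_table)) stop("incomplete table: missing AUC cell(s)")
  rounded <- if (is.finite(round_digits))
    round_half_up(auc_table, round_digits) else auc_table
  ranks <- apply(rounded, 2, function(col) rank(-col, ties.method = "average"))
  out <- data.frame(measure = rownames(auc_table) %||%
                      paste0("m", seq_len(nrow(auc_table))),
                    mean_rank = rowMeans(ranks))
  out[order(out$mean_rank), , drop = FALSE]
}

#' Construct a prediction set with exact confusion counts
#'
#' Builds a two-class `prediction_set` with exactly the requested numbers
#' of true/false positives/negatives (class 1 = positive), for studying the
#' signed-score ROC construction against the closed-form AUC bounds.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return a `prediction_set` of `tp + fn + tn + fp` objects.
#' @seealso [ideal_ad()], [auc_max()], [auc_random()]
#' @export
confusion_prediction_set <- function(tp, fn, tn, fp) {
  true_class <- rep(c(1L, 1L, 2L, 2L), c(tp, fn, tn, fp))
  predicted <- rep(c(1L, 2L, 2L, 1L), c(tp, fn, tn, fp))
  p1 <- ifelse(predicted == 1L, 0.75, 0.25)
  prediction_set(predicted, p1, true_class = true_class)
}

#' Ideal AD values for a prediction set
#'
#' Assigns AD value 0 to correct predictions and 1 to errors: within each
#' predicted class every error ranks least reliable, which attains the
#' [auc_max()] bound of the signed-score ROC AUC.
#'
#' @param pred a `prediction_set` with `correct` present.
#' @return numeric AD vector.
#' @export
ideal_ad <- function(pred) {
  stopifnot(!is.null(pred$correct))
  as.numeric(!pred$correct)
}
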