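#' Reject threshold from a training-set AD quantile
#'
#' Uses the `(100 - x)`% empirical quantile (linear-interpolation
#' definition, R type 7) of the training set's AD values as the cutoff:
#' roughly the x% most extreme training objects -- and every future object
#' more extreme than them -- fall outside the applicability domain.
#'
#' @param train_ad numeric AD values of the training set.
#' @param x_percent percentage of extreme objects to exclude, in `[0, 100)`.
#' @return object of class `reject_threshold` with `strategy`, `parameter`,
#'   `threshold_value`.
#' @export
threshold_by_training_quantile <- function(train_ad, x_percent) {
  if (x_percent < 0 || x_percent >= 100)
    stop("x_percent must lie in [0, 100)")
  if (length(train_ad) == 0) stop("empty training AD values")
  thr <- stats::quantile(train_ad, (100 - x_percent) / 100, names = FALSE)
  structure(list(strategy = "training_quantile", parameter = x_percent,
                 threshold_value = thr),
            class = "reject_threshold")
}

#' Reject threshold limiting the expected maximum local error rate
#'
#' Walks a predictiveness curve from the most reliable bin upward and places
#' the cutoff after the last bin such that the local error rate of that bin
#' and of every earlier bin stays at or below `limit`. If already the first
#' bin violates the limit, everything is rejected (with a warning).
#'
#' @param curve a `curve_data` of kind `"predictiveness"` (from
#'   [predictiveness_curve()]).
#' @param limit maximum tolerated local error rate, in (0, 1].
#' @return a `reject_threshold`; its `quantile` field is the retained
#'   fraction of the data.
#' @export
threshold_by_local_error <- function(curve, limit) {
  if (!inherits(curve, "curve_data") || curve$kind != "predictiveness")
    stop("threshold_by_local_error needs a predictiveness curve")
  ok <- cumsum(curve$ys > limit) == 0   # bin and all earlier bins pass
  cutoffs <- attr(curve, "ad_cutoffs")
  if (!any(ok)) {
    warning("no bin satisfies the local error limit; rejecting everything")
    j <- 0L
    thr <- -Inf
  } else {
    j <- max(which(ok))
    thr <- cutoffs[j]
  }
  structure(list(strategy = "local_error_limit", parameter = limit,
                 threshold_value = thr,
                 quantile = j / length(curve$ys)),
            class = "reject_threshold")
}

#' Reject threshold from a target overall accuracy
#'
#' Places the cutoff at the largest quantile `nu` of the cumulative
#' accuracy curve with `CA(nu) >= target`: the largest portion of the data
#' that can be predicted while keeping the expected overall accuracy at the
#' target. If no quantile reaches the target, everything is rejected (with
#' a warning).
#'
#' @param ca a `curve_data` of kind `"cumulative_accuracy"` (from
#'   [cumulative_accuracy_curve()]).
#' @param target required accuracy among retained predictions, in (0, 1].
#' @return a `reject_threshold`; its `quantile` field is the retained
#'   fraction of the data.
#' @export
threshold_by_accuracy_target <- function(ca, target) {
  if (!inherits(ca, "curve_data") || ca$kind != "cumulative_accuracy")
    stop("threshold_by_accuracy_target needs a cumulative accuracy curve")
  ok <- ca$ys >= target
  cutoffs <- attr(ca, "ad_cutoffs")
  if (!any(ok)) {
    warning("accuracy target unreachable at every quantile; rejecting everything")
    nu <- 0
    thr <- -Inf
  } else {
    j <- max(which(ok))
    nu <- ca$xs[j]
    thr <- cutoffs[j]
  }
  structure(list(strategy = "accuracy_target", parameter = target,
                 threshold_value = thr, quantile = nu),
            class = "reject_threshold")
}

#' Apply a reject threshold and report the coverage/error trade-off
#'
#' Objects with AD value at or below the threshold are inside the
#' applicability domain (predictions accepted); the rest are rejected.
#'
#' @param ad numeric AD values of the evaluated objects.
#' @param thr a `reject_threshold`.
#' @param pred the accompanying `prediction_set` with `correct` present.
#' @return list with `coverage` (fraction retained), `error_rate_inside`,
#'   `error_rate_outside` (`NaN` when a partition is empty), `n_inside`,
#'   `n_outside`.
#' @export
apply_reject <- function(ad, thr, pred) {
  stopifnot(inherits(thr, "reject_threshold"),
            inherits(pred, "prediction_set"), !is.null(pred$correct),
            length(ad) == length(pred$correct))
  inside <- ad <= thr$threshold_value
  list(coverage = mean(inside),
       error_rate_inside = mean(!pred$correct[inside]),
       error_rate_outside = mean(!pred$correct[!inside]),
       n_inside = sum(inside), n_outside = sum(!inside))
}
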