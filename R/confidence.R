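#' Ensemble-averaged class-1 probability
#'
#' Arithmetic mean of per-member probability estimates for class 1 (the
#' tree-averaged prediction score of a random forest, or the averaged output
#' of a network ensemble). With member probabilities rounded to 0/1 it
#' coincides with the vote fraction.
#'
#' @param member_probs numeric vector of per-member class-1 probabilities.
#' @return scalar mean probability in `[0, 1]`.
#' @export
ensemble_average_probability <- function(member_probs) {
  if (length(member_probs) == 0) stop("empty ensemble")
  if (any(member_probs < 0 | member_probs > 1))
    stop("member probabilities must lie in [0, 1]")
  mean(member_probs)
}

#' Majority vote fraction of an ensemble
#'
#' The fraction of ensemble members voting for the majority class
#' ("concordance"). An exact 50/50 tie resolves to class 1. The derived AD
#' value is `1 - nu_hat`.
#'
#' @param member_classes vector of member votes in `{1, 2}`.
#' @return list with `nu_hat` (majority vote fraction) and
#'   `predicted_class`.
#' @export
vote_fraction <- function(member_classes) {
  if (length(member_classes) == 0) stop("empty ensemble")
  stopifnot(all(member_classes %in% c(1L, 2L)))
  v1 <- mean(member_classes == 1L)
  if (v1 >= 0.5) list(nu_hat = v1, predicted_class = 1L)
  else list(nu_hat = 1 - v1, predicted_class = 2L)
}

#' CLASS-LAG of a regression-mode class prediction
#'
#' With regression targets 1 (class 1) and 0 (class 2), the smaller of the
#' two deviations `min(|0 - y_hat|, |1 - y_hat|)`: the smaller estimated
#' error probability. Defined for unbounded `y_hat` as well.
#'
#' @param y_hat regression output(s).
#' @return nonnegative AD value(s).
#' @export
class_lag <- function(y_hat) {
  pmin(abs(y_hat), abs(1 - y_hat))
}

#' Sample standard deviation of ensemble member outputs
#'
#' Ensemble spread as a confidence measure (STD): widely varying member
#' predictions flag unreliable objects. Sample (n-1) convention.
#'
#' @param member_outputs numeric vector with at least 2 entries.
#' @return nonnegative scalar.
#' @export
ensemble_std <- function(member_outputs) {
  if (length(member_outputs) < 2) stop("ensemble STD needs >= 2 members")
  stats::sd(member_outputs)
}

#' PROB-STD: normal tail area beyond the 0.5 decision value
#'
#' Combines the regression-mode prediction `y_hat` and the ensemble spread
#' `sigma_hat` into the minimum of the two normal tail areas around the 0.5
#' decision value, i.e. `pnorm(-|y_hat - 0.5| / sigma_hat)`: the estimated
#' probability mass on the wrong side of the decision boundary. At
#' `sigma_hat = 0` the continuous limit is used: 0 away from the boundary,
#' 0.5 exactly on it.
#'
#' @param y_hat regression output(s).
#' @param sigma_hat nonnegative ensemble standard deviation(s).
#' @return AD value(s) in `[0, 0.5]`.
#' @export
prob_std <- function(y_hat, sigma_hat) {
  if (any(sigma_hat < 0)) stop("sigma_hat must be nonnegative")
  out <- ifelse(sigma_hat == 0,
                ifelse(y_hat == 0.5, 0.5, 0),
                stats::pnorm(-abs(y_hat - 0.5) / sigma_hat))
  unname(out)
}

#' Weighted-majority confidence of a boosted classifier
#'
#' For AdaBoost.M1 member outputs `h_i` in `{-1, +1}` with positive weights
#' `alpha_i`, computes the decision function `F = sum(alpha_i * h_i)` and
#' its weight-normalized version `f = sum(alpha_i / sum(alpha) * h_i)` in
#' `[-1, 1]` -- a weighted majority vote whose absolute value `|f|` is the
#' absolute margin. The predicted label is the sign of `F`; the derived AD
#' value is `1 - |f|` (averaged over bootstrap replicates when boosting is
#' bagged, see [fit_predict()]).
#'
#' @param alphas positive member weights.
#' @param member_outputs member votes in `{-1, +1}`.
#' @return list with `f` (normalized margin vote) and `F` (unnormalized
#'   decision value).
#' @export
boosting_confidence <- function(alphas, member_outputs) {
  if (length(alphas) != length(member_outputs)) stop("length mismatch")
  if (sum(alphas) <= 0) stop("weights must have positive sum")
  stopifnot(all(member_outputs %in% c(-1, 1)))
  F_val <- sum(alphas * member_outputs)
  list(f = F_val / sum(alphas), F = F_val)
}

#' Logistic transform of a boosting decision value into a probability
#'
#' `p(1|x) = 1 / (1 + exp(-2 F))`; strictly increasing in `F`, hence
#' rank-equivalent to the margin for every rank-based benchmark criterion.
#'
#' @param F boosting decision value(s).
#' @return probability estimate(s) in (0, 1).
#' @export
margin_to_probability <- function(F) {
  1 / (1 + exp(-2 * F))
}

#' Platt scaling: logistic calibration of decision values
#'
#' Fits the one-dimensional logistic regression
#' `p(y = 1 | decval) = sigm(w0 + w1 * decval)` that maps raw classifier
#' decision values to class-membership probabilities. The map is strictly
#' monotone, so it never changes the rank order of the scores (and hence no
#' rank-based benchmark criterion). For SVMs the decision values fed to the
#' fit should come from an internal cross-validation of the training set
#' (see [fit_predict()]), not from resubstitution.
#'
#' @param decision_values numeric vector of raw scores.
#' @param labels vector in `{0, 1}` (1 = class with target 1).
#' @return list with `w0`, `w1` and `predict(decval)` returning calibrated
#'   probabilities.
#' @export
platt_calibrate <- function(decision_values, labels) {
  stopifnot(length(decision_values) == length(labels),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("Platt calibration needs both classes among the labels")
  fit <- suppressWarnings(
    stats::glm(labels ~ decision_values, family = stats::binomial()))
  w <- unname(stats::coef(fit))
  list(w0 = w[1], w1 = w[2],
       predict = function(decval) stats::plogis(w[1] + w[2] * decval))
}

#' Assemble the confidence AD measures a classifier family supports
#'
#' Maps a [fit_predict()] output to every confidence measure defined for its
#' family, all oriented so that larger values flag less reliable
#' predictions (error-probability orientation):
#' * every family: `p_hat_error = 1 - p_hat` (one minus the class-probability
#'   estimate of the predicted class);
#' * regression-mode ensembles (RF, NN): additionally `class_lag`, `std`
#'   (ensemble spread) and `prob_std`;
#' * regression-mode SVM: `class_lag`;
#' * MB (bagged boosting): `margin_error = 1 - |f_bar|` and
#'   `vote_error = 1 - nu_hat`.
#'
#' @param pred a `prediction_set` from [fit_predict()] / [run_cv()].
#' @param spec the [classifier_spec()] that produced it.
#' @return data.frame of per-object AD values, one column per measure,
#'   with attribute `category = "confidence"`.
#' @export
collect_confidence <- function(pred, spec) {
  stopifnot(inherits(pred, "prediction_set"))
  if (spec$family == "MB") {
    # the probability transform of the margin is rank-identical to the
    # margin itself, so the margin carries the class-probability role here
    out <- data.frame(margin_error = 1 - abs(pred$f_bar),
                      vote_error = 1 - pred$nu_hat)
  } else if (spec$mode == "regression") {
    # class_lag is the error-probability orientation of the regression-mode
    # class-probability estimate (1 - p_hat for bounded y_hat)
    out <- data.frame(class_lag = class_lag(pred$y_hat))
    if (spec$family %in% c("RF", "NN")) {
      out$std <- pred$sigma_hat
      out$prob_std <- prob_std(pred$y_hat, pred$sigma_hat)
    }
  } else {
    out <- data.frame(p_hat_error = pred$p_hat_error %||% (1 - pred$p_hat))
  }
  attr(out, "category") <- "confidence"
  out
}
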