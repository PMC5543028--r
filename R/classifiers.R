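#' Specification of a classifier family with frozen hyperparameters
#'
#' The six benchmarked families with documented fixed defaults (no
#' hyperparameter optimization anywhere in the pipeline):
#' * `RF` -- random forest, `n_tree = 500`; regression mode uses the
#'   library's native regression-tree defaults.
#' * `NN` -- ensemble of `n_members = 5` single-hidden-layer networks
#'   (`size` hidden units, weight `decay`); softmax outputs in
#'   classification mode, sigmoid output with squared-error loss in
#'   regression mode.
#' * `SVM` -- RBF kernel, `cost = 1`, kernel width `gamma = 1/p`;
#'   classification probabilities via Platt scaling fitted on fivefold
#'   cross-validated decision values of the training set.
#' * `MB` -- bagging (`n_bag = 10` bootstrap replicates) of AdaBoost.M1
#'   with `n_boost = 100` decision stumps.
#' * `kNN` -- `k = 5` nearest neighbors (Euclidean distance on continuous,
#'   Tanimoto on binary descriptors).
#' * `LDA` -- plain linear discriminant analysis.
#'
#' Regression mode (targets `y = 1` for class 1, `y = 0` for class 2,
#' decision threshold 0.5) is defined for RF, NN and SVM only.
#'
#' @param family one of `"RF"`, `"NN"`, `"SVM"`, `"MB"`, `"kNN"`, `"LDA"`.
#' @param mode `"classification"` or `"regression"`.
#' @param n_tree,n_members,n_boost,n_bag,k,size,decay,maxit,cost,gamma
#'   frozen hyperparameters, see above; `gamma = NULL` means `1/p`.
#' @param seed integer seed for every stochastic component of the fit.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("RF", "NN", "SVM", "MB", "kNN", "LDA"),
                            mode = c("classification", "regression"),
                            n_tree = 500, n_members = 5, n_boost = 100,
                            n_bag = 10, k = 5, size = 5, decay = 0.1,
                            maxit = 200, cost = 1, gamma = NULL, seed = 1) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (mode == "regression" && !family %in% c("RF", "NN", "SVM"))
    stop("regression mode is defined for RF, NN and SVM only")
  structure(list(family = family, mode = mode, n_tree = n_tree,
                 n_members = n_members, n_boost = n_boost, n_bag = n_bag,
                 k = k, size = size, decay = decay, maxit = maxit,
                 cost = cost, gamma = gamma, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
format.classifier_spec <- function(x, ...) {
  paste0(names(x), " = ", vapply(x, function(v)
    if (is.null(v)) "auto" else as.character(v), character(1)),
    collapse = "\n")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write / read a classifier specification as plain-text key = value lines
#' @param spec a [classifier_spec()].
#' @param path file path.
#' @return `read_classifier_spec` returns a [classifier_spec()].
#' @export
write_classifier_spec <- function(spec, path) {
  writeLines(format(spec), path)
  invisible(path)
}

#' @rdname write_classifier_spec
#' @export
read_classifier_spec <- function(path) {
  kv <- read.dcf(textConnection(gsub(" = ", ": ", readLines(path))))
  args <- as.list(as.data.frame(kv, stringsAsFactors = FALSE))
  num <- setdiff(names(args), c("family", "mode", "gamma"))
  args[num] <- lapply(args[num], as.numeric)
  args$gamma <- if (identical(args$gamma, "auto")) NULL else as.numeric(args$gamma)
  do.call(classifier_spec, args)
}

# internal PredictionSet constructor; p1 = probability of class 1
prediction_set <- function(predicted_class, p1, y_hat = NULL,
                           member_outputs = NULL, decision_value = NULL,
                           sigma_hat = NULL, f_bar = NULL, nu_hat = NULL,
                           true_class = NULL) {
  p1c <- pmin(pmax(p1, 0), 1)
  out <- list(predicted_class = as.integer(predicted_class),
              p1 = p1,
              p_hat = ifelse(predicted_class == 1L, p1c, 1 - p1c),
              # error probability of the predicted class, computed as the
              # smaller of the two class probabilities so that the
              # regression-mode CLASS-LAG identity holds bit-exactly
              p_hat_error = pmin(p1c, 1 - p1c),
              y_hat = y_hat, member_outputs = member_outputs,
              decision_value = decision_value, sigma_hat = sigma_hat,
              f_bar = f_bar, nu_hat = nu_hat,
              true_class = if (is.null(true_class)) NULL else as.integer(true_class))
  if (!is.null(true_class))
    out$correct <- out$predicted_class == out$true_class
  structure(out, class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("prediction_set: %d objects", length(x$predicted_class)))
  if (!is.null(x$correct))
    cat(sprintf(", accuracy %.3f", mean(x$correct)))
  cat("\n")
  invisible(x)
}

# class from regression output / class-1 probability; ties at 0.5 -> class 1
class_from_score <- function(s) ifelse(s >= 0.5, 1L, 2L)

#' Fit a classifier family and predict a test set
#'
#' Delegates learning to the established library implementation of the
#' family (randomForest, nnet, e1071, MASS; the bagged boosted stumps are
#' computed in-package) and fills every prediction field the family
#' supports: class-1 probability and predicted class always; raw ensemble
#' member outputs and their spread for RF/NN ensembles; regression output
#' `y_hat` in regression mode; decision values for SVM; normalized margins
#' and vote fractions for MB. All randomness is controlled by `spec$seed`;
#' the caller's RNG state is untouched.
#'
#' @param spec a [classifier_spec()].
#' @param train a [labeled_dataset()] with both classes present.
#' @param test_X test descriptor matrix.
#' @return a `prediction_set`.
#' @export
fit_predict <- function(spec, train, test_X) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "labeled_dataset"))
  if (length(unique(train$y)) < 2)
    stop("degenerate training data: only one class present")
  test_X <- as.matrix(test_X)
  if (ncol(test_X) != ncol(train$X)) stop("test descriptor dimension mismatch")
  fitter <- switch(spec$family,
                   RF = fit_rf, NN = fit_nn, SVM = fit_svm,
                   MB = fit_mb, kNN = fit_knn, LDA = fit_lda)
  fitter(spec, train, test_X)
}

fit_rf <- function(spec, train, test_X) {
  if (spec$mode == "classification") {
    yf <- factor(train$y, levels = c(1L, 2L))
    rf <- with_seed(spec$seed,
      randomForest::randomForest(x = train$X, y = yf, ntree = spec$n_tree))
    pr <- predict(rf, test_X, predict.all = TRUE)
    member <- (pr$individual == "1") * 1
    p1 <- rowMeans(member)
    prediction_set(class_from_score(p1), p1, member_outputs = member)
  } else {
    y01 <- as.numeric(train$y == 1L)
    # 0/1 targets are intentional: regression trees estimate p(1|x)
    rf <- with_seed(spec$seed, suppressWarnings(
      randomForest::randomForest(x = train$X, y = y01, ntree = spec$n_tree)))
    pr <- predict(rf, test_X, predict.all = TRUE)
    y_hat <- unname(pr$aggregate)
    prediction_set(class_from_score(y_hat), y_hat, y_hat = y_hat,
                   member_outputs = pr$individual,
                   sigma_hat = apply(pr$individual, 1, stats::sd))
  }
}

fit_nn <- function(spec, train, test_X) {
  p <- ncol(train$X)
  max_nwts <- (p + 1) * spec$size + (spec$size + 1) * 2 + 100
  members <- lapply(seq_len(spec$n_members), function(i) {
    if (spec$mode == "classification") {
      targets <- cbind(c1 = as.numeric(train$y == 1L),
                       c2 = as.numeric(train$y == 2L))
      fit <- with_seed(spec$seed + i - 1L,
        nnet::nnet(train$X, targets, size = spec$size, decay = spec$decay,
                   maxit = spec$maxit, softmax = TRUE, MaxNWts = max_nwts,
                   trace = FALSE))
      predict(fit, test_X)[, "c1"]
    } else {
      y01 <- as.numeric(train$y == 1L)
      fit <- with_seed(spec$seed + i - 1L,
        nnet::nnet(train$X, y01, size = spec$size, decay = spec$decay,
                   maxit = spec$maxit, linout = FALSE, MaxNWts = max_nwts,
                   trace = FALSE))
      drop(predict(fit, test_X))
    }
  })
  member <- do.call(cbind, members)
  p1 <- rowMeans(member)
  if (spec$mode == "classification")
    prediction_set(class_from_score(p1), p1, member_outputs = member)
  else
    prediction_set(class_from_score(p1), p1, y_hat = p1,
                   member_outputs = member,
                   sigma_hat = apply(member, 1, stats::sd))
}

fit_svm <- function(spec, train, test_X) {
  gamma <- spec$gamma %||% (1 / ncol(train$X))
  if (spec$mode == "classification") {
    yf <- factor(train$y, levels = c(1L, 2L))
    sv <- with_seed(spec$seed,
      e1071::svm(x = train$X, y = yf, kernel = "radial", cost = spec$cost,
                 gamma = gamma, scale = FALSE))
    dv_test <- drop(attr(predict(sv, test_X, decision.values = TRUE),
                         "decision.values"))
    # Platt scaling on fivefold cross-validated training decision values
    y01 <- as.numeric(train$y == 1L)
    folds <- kfold_split(length(train$y), K = 5, seed = spec$seed + 1L,
                         labels = train$y)
    dv_cv <- numeric(length(train$y))
    for (f in seq_len(folds$K)) {
      in_f <- folds$fold_id == f
      sv_f <- with_seed(spec$seed + f,
        e1071::svm(x = train$X[!in_f, , drop = FALSE], y = yf[!in_f],
                   kernel = "radial", cost = spec$cost, gamma = gamma,
                   scale = FALSE))
      dv_cv[in_f] <- drop(attr(predict(sv_f, train$X[in_f, , drop = FALSE],
                                       decision.values = TRUE),
                               "decision.values"))
    }
    cal <- platt_calibrate(dv_cv, y01)
    p1 <- cal$predict(dv_test)
    prediction_set(class_from_score(p1), p1, decision_value = dv_test)
  } else {
    y01 <- as.numeric(train$y == 1L)
    sv <- with_seed(spec$seed,
      e1071::svm(x = train$X, y = y01, type = "eps-regression",
                 kernel = "radial", cost = spec$cost, gamma = gamma,
                 scale = FALSE))
    y_hat <- unname(predict(sv, test_X))
    prediction_set(class_from_score(y_hat), y_hat, y_hat = y_hat)
  }
}

fit_knn <- function(spec, train, test_X) {
  metric <- if (train$feature_kind == "binary") "tanimoto" else "euclidean"
  d <- pairwise_distances(test_X, train$X, metric)
  n_train <- nrow(train$X)
  if (spec$k > n_train) stop("k exceeds the number of training objects")
  is1 <- train$y == 1L
  p1 <- vapply(seq_len(nrow(d)), function(i) {
    nn <- order(d[i, ], seq_len(n_train))[seq_len(spec$k)]
    mean(is1[nn])
  }, numeric(1))
  prediction_set(class_from_score(p1), p1)
}

fit_lda <- function(spec, train, test_X) {
  fit <- suppressWarnings(
    MASS::lda(train$X, grouping = factor(train$y, levels = c(1L, 2L))))
  p1 <- unname(predict(fit, test_X)$posterior[, "1"])
  prediction_set(class_from_score(p1), p1)
}

## --- bagged AdaBoost.M1 with decision stumps (MB) ------------------------

# weighted decision stump: find (feature, threshold, polarity) minimizing
# weighted 0/1 error; ord = list of per-feature sort orders (precomputed)
best_stump <- function(X, y_pm, w, ord) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    o <- ord[[j]]
    xs <- X[o, j]
    wp <- cumsum(w[o] * (y_pm[o] == 1))   # weight of +1 objects with x <= cut
    wn <- cumsum(w[o] * (y_pm[o] == -1))
    W_neg <- wn[length(wn)]
    # cut after position i (threshold between xs[i] and xs[i+1]);
    # i = 0 puts every object above the threshold
    err_pos <- c(W_neg, wp + W_neg - wn)  # rule: +1 if x > t
    valid <- c(TRUE, xs[-length(xs)] != xs[-1])
    valid[length(valid) + 1] <- TRUE      # cut above all values
    err_neg <- 1 - err_pos                # polarity flip (weights sum to 1)
    err_pos[!valid] <- Inf
    err_neg[!valid] <- Inf
    i_pos <- which.min(err_pos)
    i_neg <- which.min(err_neg)
    use_pos <- err_pos[i_pos] <= err_neg[i_neg]
    e <- if (use_pos) err_pos[i_pos] else err_neg[i_neg]
    if (e < best$err) {
      i_best <- if (use_pos) i_pos else i_neg
      thr <- if (i_best == 1) xs[1] - 1
             else if (i_best > length(xs)) xs[length(xs)] + 1
             else (xs[i_best - 1] + xs[i_best]) / 2
      best <- list(err = e, feature = j, threshold = thr,
                   polarity = if (use_pos) 1 else -1)
    }
  }
  best
}

stump_predict <- function(stump, data) {
  ifelse(data[, stump$feature] > stump$threshold,
         stump$polarity, -stump$polarity)
}

# AdaBoost.M1 on decision stumps; y_pm in {-1,+1}
fit_adaboost <- function(X, y_pm, n_boost) {
  n <- nrow(X)
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  w <- rep(1 / n, n)
  stumps <- vector("list", n_boost)
  alphas <- numeric(n_boost)
  m <- 0L
  for (b in seq_len(n_boost)) {
    st <- best_stump(X, y_pm, w, ord)
    eps <- max(min(st$err, 1 - 1e-10), 1e-10)
    if (eps >= 0.5) break
    alpha <- 0.5 * log((1 - eps) / eps)
    h <- stump_predict(st, X)
    w <- w * exp(-alpha * y_pm * h)
    w <- w / sum(w)
    m <- m + 1L
    stumps[[m]] <- st
    alphas[m] <- alpha
  }
  list(stumps = stumps[seq_len(m)], alphas = alphas[seq_len(m)])
}

adaboost_decision <- function(model, X) {
  if (length(model$stumps) == 0) return(numeric(nrow(X)))
  H <- vapply(model$stumps, stump_predict, numeric(nrow(X)), data = X)
  drop(H %*% model$alphas)
}

fit_mb <- function(spec, train, test_X) {
  y_pm <- ifelse(train$y == 1L, 1, -1)
  n <- nrow(train$X)
  bag_idx <- with_seed(spec$seed,
    replicate(spec$n_bag, sample(n, n, replace = TRUE), simplify = FALSE))
  per_bag <- lapply(bag_idx, function(idx) {
    model <- fit_adaboost(train$X[idx, , drop = FALSE], y_pm[idx],
                          spec$n_boost)
    F_test <- adaboost_decision(model, test_X)
    a_sum <- sum(model$alphas)
    list(f = if (a_sum > 0) F_test / a_sum else numeric(nrow(test_X)),
         F = F_test)
  })
  f_mat <- vapply(per_bag, `[[`, numeric(nrow(test_X)), "f")
  F_mat <- vapply(per_bag, `[[`, numeric(nrow(test_X)), "F")
  f_bar <- rowMeans(f_mat)
  votes <- sign(F_mat)
  votes[votes == 0] <- 1
  nu_hat <- pmax(rowMeans(votes == 1), rowMeans(votes == -1))
  p1 <- (1 + f_bar) / 2
  prediction_set(class_from_score(p1), p1, member_outputs = f_mat,
                 decision_value = rowMeans(F_mat), f_bar = f_bar,
                 nu_hat = nu_hat)
}
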