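#' DA-index of a query object against a training set
#'
#' The DA-index is a k-nearest-neighbor novelty triple:
#' * `kappa` -- distance to the kth-nearest training neighbor,
#' * `gamma` -- mean distance to the k nearest neighbors,
#' * `delta` -- length of the mean difference vector from the query to its k
#'   nearest neighbors; small when the query is well embedded (symmetric
#'   neighbors cancel), large under extrapolation.
#'
#' Neighbors are selected under the chosen metric; distance ties at rank k
#' are broken by training-set index order. `delta` is always computed in raw
#' descriptor space with the Euclidean norm, also when neighbors were picked
#' by Tanimoto distance (Tanimoto induces no vector geometry, so the
#' mean-vector length is the only meaningful reading of delta there; note
#' that on that scale `delta <= gamma` need not hold). Under the Euclidean
#' metric the chain `delta <= gamma <= kappa` is a vector-norm identity.
#'
#' @param train_X training descriptor matrix (>= k rows).
#' @param query single descriptor vector.
#' @param k neighbor count (default 5).
#' @param metric `"euclidean"` or `"tanimoto"`.
#' @return named numeric vector `c(kappa, gamma, delta)`.
#' @export
da_index <- function(train_X, query, k = 5,
                     metric = c("euclidean", "tanimoto")) {
  metric <- match.arg(metric)
  train_X <- as.matrix(train_X)
  if (k > nrow(train_X))
    stop("k exceeds the number of training objects")
  if (length(query) != ncol(train_X)) stop("query dimension mismatch")
  d <- drop(pairwise_distances(matrix(query, 1L), train_X, metric))
  nn <- order(d, seq_along(d))[seq_len(k)]
  diffs <- sweep(train_X[nn, , drop = FALSE], 2, query)
  c(kappa = d[nn[k]],
    gamma = mean(d[nn]),
    delta = sqrt(sum(colMeans(diffs)^2)))
}

#' Cosine novelty measure of a query object
#'
#' One minus the mean cosine similarity of the query to its k nearest
#' training neighbors, where neighbors are the k training objects with the
#' largest cosine similarity to the query. Zero for a query parallel to its
#' neighbors; up to 2 on signed (autoscaled) descriptors.
#'
#' @inheritParams da_index
#' @return nonnegative scalar AD value.
#' @export
cosine_ad <- function(train_X, query, k = 5) {
  train_X <- as.matrix(train_X)
  if (k > nrow(train_X))
    stop("k exceeds the number of training objects")
  s <- drop(pairwise_cosine(matrix(query, 1L), train_X))
  nn <- order(-s, seq_along(s))[seq_len(k)]
  1 - mean(s[nn])
}

#' All label-free novelty scores for a set of test objects
#'
#' Computes the per-object novelty AD values against the training objects of
#' `train`: the Euclidean DA-index (`kappa_euc`, `gamma_euc`, `delta_euc`),
#' the Tanimoto DA-index (`kappa_tan`, `gamma_tan`, `delta_tan`; only when
#' the descriptors are nonnegative, since Tanimoto is undefined otherwise)
#' and the cosine measure (`cos_ad`). Class labels are never read.
#'
#' When `test_X` is `NULL` the training objects score themselves
#' leave-self-out: each object's own row is excluded from its neighbor
#' search, mirroring a cross-validation design where test objects are
#' disjoint from the training set.
#'
#' @param train a [labeled_dataset()] (only its `X` is used).
#' @param test_X test descriptor matrix, or `NULL` for leave-self-out
#'   self-scoring of the training set.
#' @param k neighbor count (default 5, used for every measure).
#' @return data.frame of per-object AD values, one column per measure,
#'   with attribute `category = "novelty"`.
#' @export
score_novelty <- function(train, test_X = NULL, k = 5) {
  train_X <- if (inherits(train, "labeled_dataset")) train$X else as.matrix(train)
  self <- is.null(test_X)
  test_X <- if (self) train_X else as.matrix(test_X)
  n_train <- nrow(train_X)
  if (k + self > n_train)
    stop("k exceeds the number of available training neighbors")
  with_tan <- all(train_X >= 0) && all(test_X >= 0)

  score_metric <- function(metric) {
    d <- pairwise_distances(test_X, train_X, metric)
    if (self) diag(d) <- Inf
    t(vapply(seq_len(nrow(d)), function(i) {
      nn <- order(d[i, ], seq_len(n_train))[seq_len(k)]
      diffs <- sweep(train_X[nn, , drop = FALSE], 2, test_X[i, ])
      c(d[i, nn[k]], mean(d[i, nn]), sqrt(sum(colMeans(diffs)^2)))
    }, numeric(3)))
  }

  euc <- score_metric("euclidean")
  out <- data.frame(kappa_euc = euc[, 1], gamma_euc = euc[, 2],
                    delta_euc = euc[, 3])
  if (with_tan) {
    tan <- score_metric("tanimoto")
    out$kappa_tan <- tan[, 1]
    out$gamma_tan <- tan[, 2]
    out$delta_tan <- tan[, 3]
  }
  s <- pairwise_cosine(test_X, train_X)
  if (self) diag(s) <- -Inf
  out$cos_ad <- vapply(seq_len(nrow(s)), function(i) {
    nn <- order(-s[i, ], seq_len(n_train))[seq_len(k)]
    1 - mean(s[i, nn])
  }, numeric(1))
  attr(out, "category") <- "novelty"
  out
}
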