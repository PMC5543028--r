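#' Autoscale a descriptor matrix
#'
#' Column-wise standardization: subtract the column mean, then divide by the
#' column standard deviation (sample convention, n-1 denominator). The
#' centers and scales are returned so future objects can be transformed
#' identically. Following common practice for this kind of benchmark,
#' scaling is fit on the entire data matrix before cross-validation by
#' default (see [run_benchmark()]); binary fingerprint descriptors are not
#' autoscaled.
#'
#' @param X numeric descriptor matrix.
#' @return list with `X` (scaled matrix), `centers`, `scales`.
#' @seealso [autoscale_apply()]
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  bad <- which(scales == 0)
  if (length(bad))
    stop("constant column(s): ",
         paste(colnames(X)[bad] %||% bad, collapse = ", "))
  Xs <- sweep(sweep(X, 2, centers), 2, scales, `/`)
  list(X = Xs, centers = centers, scales = scales)
}

#' Apply a previously fitted autoscaling to new objects
#'
#' @param X numeric matrix with the same columns as the training matrix.
#' @param centers,scales as returned by [autoscale()].
#' @return the transformed matrix.
#' @export
autoscale_apply <- function(X, centers, scales) {
  sweep(sweep(as.matrix(X), 2, centers), 2, scales, `/`)
}

#' Euclidean distance between two descriptor vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  sqrt(sum((a - b)^2))
}

#' Tanimoto distance between two nonnegative descriptor vectors
#'
#' One minus the Tanimoto (Jaccard) similarity
#' `a.b / (|a|^2 + |b|^2 - a.b)`. For 0/1 vectors this reduces to
#' `1 - |intersection| / |union|`; the continuous form extends it to count
#' vectors (e.g. substructure frequencies).
#'
#' @param a,b nonnegative numeric vectors of equal length.
#' @return distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (any(a < 0) || any(b < 0)) stop("Tanimoto requires nonnegative vectors")
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) stop("Tanimoto similarity undefined for two all-zero vectors")
  1 - ab / denom
}

#' Cosine similarity between two descriptor vectors
#'
#' The inner product divided by the product of the vector lengths; the
#' cosine of the angle between the two vectors seen from the origin. On
#' nonnegative descriptors it lies in `[0, 1]`; on autoscaled (signed)
#' descriptors it can be negative, so the derived AD value `1 - cos` lies
#' in `[0, 2]`.
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero-length vector")
  sum(a * b) / (na * nb)
}

# Pairwise distance matrix (query rows x train rows), vectorized.
# metric: "euclidean" or "tanimoto".
pairwise_distances <- function(query, train, metric = c("euclidean", "tanimoto")) {
  metric <- match.arg(metric)
  query <- as.matrix(query)
  train <- as.matrix(train)
  cp <- tcrossprod(query, train)
  q2 <- rowSums(query^2)
  t2 <- rowSums(train^2)
  if (metric == "euclidean") {
    d2 <- outer(q2, t2, `+`) - 2 * cp
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    if (any(query < 0) || any(train < 0))
      stop("Tanimoto requires nonnegative descriptors")
    denom <- outer(q2, t2, `+`) - cp
    if (any(denom == 0))
      stop("Tanimoto similarity undefined for two all-zero vectors")
    1 - cp / denom
  }
}

# Pairwise cosine similarity matrix (query rows x train rows).
pairwise_cosine <- function(query, train) {
  query <- as.matrix(query)
  train <- as.matrix(train)
  nq <- sqrt(rowSums(query^2))
  nt <- sqrt(rowSums(train^2))
  if (any(nq == 0) || any(nt == 0))
    stop("cosine undefined for a zero-length vector")
  tcrossprod(query / nq, train / nt)
}
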