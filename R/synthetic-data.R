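#' Generate a two-class Gaussian descriptor dataset
#'
#' Draws two multivariate-normal classes with unit within-class variance on
#' every descriptor. A fraction of the descriptors is informative: on those
#' axes the class means sit symmetrically at `-separation/2` and
#' `+separation/2` (so the pooled mean stays at the origin and autoscaling is
#' near-neutral); the remaining descriptors carry no class signal. With
#' `p = 1`, `informative_fraction = 1` and balanced classes the Bayes
#' accuracy has the closed form `pnorm(separation / 2)`, which calibrates the
#' separation needed for a target difficulty regime.
#'
#' Class sizes are `round(n * class_ratio)` for class 1; the remainder goes
#' to class 2. The generator is a pure function of its arguments: the same
#' call yields a bit-identical dataset.
#'
#' @param n object count.
#' @param p descriptor count.
#' @param class_ratio fraction of objects in class 1, in (0, 1).
#' @param separation nonnegative mean shift per informative descriptor.
#' @param informative_fraction fraction of descriptors carrying class
#'   signal, in (0, 1]; informative descriptors are spread evenly over the
#'   descriptor index range.
#' @param seed integer RNG seed.
#' @param name dataset label.
#' @return a [labeled_dataset()] with `feature_kind = "continuous"`.
#' @export
generate_gaussian_dataset <- function(n, p, class_ratio = 0.5, separation = 1,
                                      informative_fraction = 1, seed = 1,
                                      name = "gaussian") {
  stopifnot(n >= 2, p >= 1, separation >= 0,
            informative_fraction > 0, informative_fraction <= 1)
  n1 <- round(n * class_ratio)
  n2 <- n - n1
  if (n1 < 1 || n2 < 1)
    stop("class_ratio leaves one class empty for this n")
  n_inf <- max(1L, round(p * informative_fraction))
  inf_idx <- unique(round(seq(1L, p, length.out = n_inf)))
  mu <- numeric(p)
  mu[inf_idx] <- separation / 2
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    X[seq_len(n1), ] <- sweep(X[seq_len(n1), , drop = FALSE], 2, mu, `+`)
    X[seq_len(n2) + n1, ] <- sweep(X[seq_len(n2) + n1, , drop = FALSE], 2, mu, `-`)
  })
  colnames(X) <- paste0("d", seq_len(p))
  labeled_dataset(X, rep(c(1L, 2L), c(n1, n2)), "continuous", name = name)
}

#' Generate a fingerprint-like binary descriptor dataset
#'
#' Each bit is drawn independently per object from its class-conditional
#' on-probability, emulating substructure-key fingerprints (e.g. 166-bit
#' MACCS-style vectors). Class sizes follow the same rounding rule as
#' [generate_gaussian_dataset()].
#'
#' @param n object count.
#' @param p_on_class1,p_on_class2 per-bit on-probabilities, each of length
#'   `p`, all entries in `[0, 1]`.
#' @param class_ratio fraction of objects in class 1.
#' @param seed integer RNG seed.
#' @param name dataset label.
#' @return a [labeled_dataset()] with `feature_kind = "binary"`.
#' @export
generate_fingerprint_dataset <- function(n, p_on_class1, p_on_class2,
                                         class_ratio = 0.5, seed = 1,
                                         name = "fingerprint") {
  if (length(p_on_class1) != length(p_on_class2))
    stop("probability lists must have equal length")
  if (any(p_on_class1 < 0 | p_on_class1 > 1 | p_on_class2 < 0 | p_on_class2 > 1))
    stop("bit probabilities must lie in [0, 1]")
  p <- length(p_on_class1)
  n1 <- round(n * class_ratio)
  n2 <- n - n1
  if (n1 < 1 || n2 < 1)
    stop("class_ratio leaves one class empty for this n")
  X <- with_seed(seed, {
    x1 <- matrix(stats::rbinom(n1 * p, 1L, rep(p_on_class1, each = n1)), n1, p)
    x2 <- matrix(stats::rbinom(n2 * p, 1L, rep(p_on_class2, each = n2)), n2, p)
    rbind(x1, x2)
  })
  colnames(X) <- paste0("b", seq_len(p))
  labeled_dataset(X, rep(c(1L, 2L), c(n1, n2)), "binary", name = name)
}

#' Displace a random subset of objects away from the training density
#'
#' Marks a random fraction of objects as "novel" and displaces each by a
#' vector of length `shift * sqrt(p)` in a uniformly random direction,
#' keeping its class label. This isolates the remote-but-possibly-correct
#' setting: the displaced objects are far from the data density but their
#' labels are untouched, so novelty measures should flag them regardless of
#' whether the classifier still gets them right.
#'
#' @param ds a continuous [labeled_dataset()].
#' @param fraction fraction of objects to displace, in (0, 1).
#' @param shift nonnegative displacement in units of `sqrt(p)`.
#' @param seed integer RNG seed.
#' @return the dataset with displaced rows and `novel_flag` set.
#' @export
inject_novel_objects <- function(ds, fraction, shift, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"), shift >= 0,
            fraction > 0, fraction < 1)
  if (ds$feature_kind != "continuous")
    stop("novel-object injection requires continuous descriptors")
  n <- nrow(ds$X)
  p <- ncol(ds$X)
  n_novel <- round(fraction * n)
  if (n_novel < 1) stop("fraction * n selects no objects")
  with_seed(seed, {
    idx <- sample(n, n_novel)
    dir <- matrix(stats::rnorm(n_novel * p), n_novel, p)
    dir <- dir / sqrt(rowSums(dir^2))
  })
  X <- ds$X
  X[idx, ] <- X[idx, ] + shift * sqrt(p) * dir
  flag <- rep(FALSE, n)
  flag[idx] <- TRUE
  labeled_dataset(X, ds$y, "continuous", novel_flag = flag, name = ds$name)
}
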