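# shared fixtures, all generated in code under fixed seeds

# two well-separated Gaussian blobs: every family should classify these
separable_blobs <- function(n = 200, p = 10, seed = 5) {
  generate_gaussian_dataset(n, p, class_ratio = 0.5, separation = 3,
                            informative_fraction = 0.5, seed = seed,
                            name = "blobs")
}

# intermediate-difficulty study conditions: pooled classifier AUC ~0.8
intermediate_dataset <- function(seed, n = 400, p = 40) {
  generate_gaussian_dataset(n, p, class_ratio = 0.45, separation = 0.5,
                            informative_fraction = 0.25, seed = seed,
                            name = paste0("intermediate_", seed))
}

# brute-force Mann-Whitney AUC oracle: pairwise comparison, ties count 1/2
mann_whitney_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

# prediction set with given confusion counts plus an uninformative AD draw
random_ad <- function(n, seed) with_seed_local(seed, stats::runif(n))

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
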