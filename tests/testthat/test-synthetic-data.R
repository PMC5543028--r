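test_that("generators are pure functions of their arguments", {
  a <- generate_gaussian_dataset(50, 8, class_ratio = 0.4, separation = 1, seed = 11)
  b <- generate_gaussian_dataset(50, 8, class_ratio = 0.4, separation = 1, seed = 11)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  f1 <- generate_fingerprint_dataset(40, rep(0.6, 16), rep(0.3, 16), seed = 7)
  f2 <- generate_fingerprint_dataset(40, rep(0.6, 16), rep(0.3, 16), seed = 7)
  expect_identical(f1$X, f2$X)
})

test_that("class sizes follow round(n * class_ratio), remainder to class 2", {
  for (cr in c(0.15, 0.38, 0.5, 0.62)) {
    ds <- generate_gaussian_dataset(333, 5, class_ratio = cr, seed = 1)
    expect_equal(sum(ds$y == 1L), round(333 * cr))
    expect_equal(sum(ds$y == 2L), 333 - round(333 * cr))
  }
  expect_error(generate_gaussian_dataset(100, 5, class_ratio = 0.001),
               "empty")
})

test_that("zero separation carries no class signal", {
  ds <- generate_gaussian_dataset(400, 10, separation = 0, seed = 3)
  pred <- run_cv(ds, classifier_spec("LDA"),
                 kfold_split(400, 5, seed = 3, labels = ds$y))
  base <- max(table(ds$y)) / 400
  # accuracy not significantly above the majority baseline (3 binomial SE)
  expect_lt(mean(pred$correct), base + 3 * sqrt(base * (1 - base) / 400))
})

test_that("one balanced informative descriptor attains the two-Gaussian Bayes accuracy", {
  # closed form: Bayes accuracy = pnorm(separation / 2); separation 2 -> 0.841
  ds <- generate_gaussian_dataset(4000, 1, separation = 2, seed = 9)
  pred <- run_cv(ds, classifier_spec("LDA"),
                 kfold_split(4000, 5, seed = 9, labels = ds$y))
  expect_equal(mean(pred$correct), pnorm(1), tolerance = 0.02)
})

test_that("fingerprint bits match their class-conditional on-probabilities", {
  p_on1 <- c(rep(0.8, 20), rep(0.3, 146))
  p_on2 <- c(rep(0.2, 20), rep(0.3, 146))
  ds <- generate_fingerprint_dataset(1000, p_on1, p_on2, seed = 21)
  expect_identical(ds$feature_kind, "binary")
  # with 332 simultaneous per-bit checks a few ~3 SE excursions are expected
  # sampling behavior, so test every bit at 4.5 SE (a parameter mix-up would
  # be tens of SEs off) and the bulk at 3 SE
  dev <- function(freq, p, n) abs(freq - p) / pmax(sqrt(p * (1 - p) / n), 1e-12)
  d1 <- dev(colMeans(ds$X[ds$y == 1L, ]), p_on1, sum(ds$y == 1L))
  d2 <- dev(colMeans(ds$X[ds$y == 2L, ]), p_on2, sum(ds$y == 2L))
  expect_true(all(c(d1, d2) <= 4.5))
  expect_gte(mean(c(d1, d2) <= 3), 0.97)
})

test_that("identical bit distributions give chance-level k-NN accuracy", {
  ds <- generate_fingerprint_dataset(300, rep(0.4, 32), rep(0.4, 32),
                                     class_ratio = 0.5, seed = 13)
  pred <- run_cv(ds, classifier_spec("kNN"),
                 kfold_split(300, 5, seed = 13, labels = ds$y))
  base <- max(table(ds$y)) / 300
  expect_lt(abs(mean(pred$correct) - base), 3 * sqrt(base * (1 - base) / 300))
})

test_that("degenerate all-on/all-off bits give Tanimoto 1 between, 0 within classes", {
  ds <- generate_fingerprint_dataset(10, rep(1, 8), rep(0, 8), seed = 1)
  i1 <- which(ds$y == 1L)
  i2 <- which(ds$y == 2L)
  expect_equal(tanimoto_distance(ds$X[i1[1], ], ds$X[i1[2], ]), 0)
  expect_equal(tanimoto_distance(ds$X[i1[1], ], ds$X[i2[1], ]), 1)
})

test_that("novel-object injection flags, displaces and preserves labels", {
  ds <- generate_gaussian_dataset(100, 6, seed = 4)
  out0 <- inject_novel_objects(ds, fraction = 0.1, shift = 0, seed = 2)
  expect_equal(sum(out0$novel_flag), 10)
  expect_equal(out0$X, ds$X)               # zero shift: identity displacement
  expect_identical(out0$y, ds$y)

  out <- inject_novel_objects(ds, fraction = 0.1, shift = 10, seed = 2)
  expect_identical(out$novel_flag, out0$novel_flag)
  # displacement length is shift * sqrt(p) for every flagged object
  moved <- sqrt(rowSums((out$X - ds$X)^2))
  expect_equal(unname(moved[out$novel_flag]), rep(10 * sqrt(6), 10))
  # every flagged object is farther (mean 5-NN distance to unflagged
  # objects, brute force) than every unflagged object
  ref <- out$X[!out$novel_flag, ]
  gamma_to_ref <- function(x, self_row = NULL) {
    d <- sort(apply(ref, 1, function(r) euclidean_distance(x, r)))
    if (!is.null(self_row)) d <- d[-1]   # drop self distance 0
    mean(d[1:5])
  }
  g_nov <- apply(out$X[out$novel_flag, ], 1, gamma_to_ref)
  g_ref <- sapply(which(!out$novel_flag), function(i)
    gamma_to_ref(out$X[i, ], self_row = i))
  expect_gt(min(g_nov), max(g_ref))
  expect_error(inject_novel_objects(ds, fraction = 0.001, shift = 1),
               "no objects")
})

test_that("LDA difficulty is monotone in the class separation", {
  seps <- c(0, 1, 2, 4)
  mean_auc <- sapply(seps, function(sep) {
    mean(sapply(1:5, function(s) {
      ds <- generate_gaussian_dataset(1000, 10, separation = sep,
                                      informative_fraction = 0.5, seed = s)
      pred <- run_cv(ds, classifier_spec("LDA"),
                     kfold_split(1000, 5, seed = s, labels = ds$y))
      roc_auc(pred$p1, pred$true_class == 1L)$auc
    }))
  })
  expect_true(all(diff(mean_auc) > -0.01))
  expect_lt(mean_auc[1], 0.55)
  expect_gt(mean_auc[4], 0.95)
})

test_that("dataset CSV round-trips including labels and novelty flags", {
  ds <- inject_novel_objects(generate_gaussian_dataset(40, 4, seed = 8),
                             fraction = 0.25, shift = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(unname(back$X), unname(ds$X), tolerance = 1e-12)
  expect_identical(back$y, ds$y)
  expect_identical(back$novel_flag, ds$novel_flag)
  expect_identical(back$feature_kind, "continuous")
})
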