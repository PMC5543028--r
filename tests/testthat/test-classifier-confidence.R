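test_that("confidence primitives match their closed forms", {
  expect_equal(ensemble_average_probability(c(0.6, 0.8)), 0.7)
  expect_equal(ensemble_average_probability(rep(0.37, 9)), 0.37)
  expect_error(ensemble_average_probability(numeric(0)), "empty")

  expect_equal(vote_fraction(rep(c(1L, 2L), c(73, 27))),
               list(nu_hat = 0.73, predicted_class = 1L))
  expect_equal(vote_fraction(rep(2L, 10)),
               list(nu_hat = 1, predicted_class = 2L))
  expect_equal(vote_fraction(rep(c(1L, 2L), 5)),       # exact tie -> class 1
               list(nu_hat = 0.5, predicted_class = 1L))

  expect_equal(class_lag(c(0.5, 1.0, 0.7)), c(0.5, 0, 0.3))

  expect_equal(ensemble_std(rep(0.4, 6)), 0)
  expect_equal(ensemble_std(c(0, 1)), sqrt(0.5))        # n-1 convention
  expect_equal(ensemble_std(3 * c(0.1, 0.5, 0.9)),
               3 * ensemble_std(c(0.1, 0.5, 0.9)))

  expect_equal(prob_std(0.5, 2), 0.5)
  expect_equal(prob_std(0.8, 0.3), pnorm(-1))
  expect_equal(prob_std(0.8, 0), 0)                     # sigma -> 0 limit
  expect_equal(prob_std(0.5, 0), 0.5)
  expect_error(prob_std(0.5, -1), "nonnegative")

  expect_equal(boosting_confidence(c(0.2, 5), c(1, 1))$f, 1)
  bc <- boosting_confidence(c(2, 1), c(1, -1))
  expect_equal(bc$f, 1 / 3)
  expect_equal(bc$F, 1)
  neg <- boosting_confidence(c(2, 1), c(-1, 1))
  expect_equal(neg$f, -bc$f)                            # vote symmetry

  expect_equal(margin_to_probability(0), 0.5)
  expect_equal(margin_to_probability(1), 1 / (1 + exp(-2)))
  expect_equal(margin_to_probability(0.7) + margin_to_probability(-0.7), 1)
})

test_that("orientation: less decisive outputs never get smaller AD values", {
  y_grid <- seq(0.5, 1, by = 0.05)       # moving y_hat toward 0.5
  expect_true(all(diff(class_lag(y_grid)) <= 0))
  expect_true(all(diff(prob_std(y_grid, 0.2)) <= 0))
  f_grid <- seq(0, 1, by = 0.05)          # reducing |f| raises margin error
  expect_true(all(diff(1 - abs(f_grid)) <= 0))
})

test_that("averaged 0/1 member probabilities equal the vote fraction", {
  with_seed_local(8, {
    for (i in 1:10) {
      votes <- sample(c(1L, 2L), 25, replace = TRUE)
      vf <- vote_fraction(votes)
      pbar <- ensemble_average_probability(as.numeric(votes == 1L))
      expect_equal(max(pbar, 1 - pbar), vf$nu_hat)
    }
  })
})

test_that("platt scaling recovers sigmoid parameters and preserves ranks", {
  w0 <- -1; w1 <- 2
  rel_err <- sapply(1:5, function(s) {
    with_seed_local(s, {
      dv <- rnorm(2000)
      lab <- rbinom(2000, 1, plogis(w0 + w1 * dv))
    })
    cal <- platt_calibrate(dv, lab)
    c(abs(cal$w0 - w0) / abs(w0), abs(cal$w1 - w1) / abs(w1))
  })
  expect_lt(median(rel_err), 0.1)          # typical recovery within 10%
  expect_true(all(rel_err < 0.25))         # every draw in the right regime
  # strictly monotone map: Kendall tau with the raw decision values is 1
  with_seed_local(12, dv <- rnorm(200))
  cal <- platt_calibrate(dv, as.numeric(dv + rnorm(200) > 0))
  expect_equal(cor(dv, cal$predict(dv), method = "kendall"), 1)
  expect_error(platt_calibrate(dv, rep(1, 200)), "both classes")
})

test_that("k-NN probabilities are neighbor class fractions with deterministic ties", {
  # five training points at distinct distances, labels 1,1,1,2,2
  train <- labeled_dataset(matrix(c(1, 2, 3, 4, 5), ncol = 1),
                           c(1L, 1L, 1L, 2L, 2L), "continuous")
  pred <- fit_predict(classifier_spec("kNN", k = 5), train,
                      matrix(0, ncol = 1))
  expect_equal(pred$predicted_class, 1L)
  expect_equal(pred$p_hat, 0.6)
  # 2-of-5 neighbors of class 1 -> class 2 with p_hat 0.6
  train2 <- labeled_dataset(matrix(1:5, ncol = 1),
                            c(1L, 1L, 2L, 2L, 2L), "continuous")
  pred2 <- fit_predict(classifier_spec("kNN", k = 5), train2,
                       matrix(0, ncol = 1))
  expect_equal(pred2$predicted_class, 2L)
  expect_equal(pred2$p_hat, 0.6)
})

test_that("CLASS-LAG from k-NN probabilities equals 1 - p_hat bit-exactly", {
  ds <- generate_gaussian_dataset(150, 6, separation = 1, seed = 17)
  pred <- run_cv(ds, classifier_spec("kNN"),
                 kfold_split(150, 5, seed = 17, labels = ds$y))
  expect_identical(class_lag(pred$p1), pred$p_hat_error)
})

test_that("every family solves linearly separable data in cross-validation", {
  ds <- separable_blobs()
  folds <- kfold_split(nrow(ds$X), 5, seed = 1, labels = ds$y)
  for (fam in c("RF", "NN", "SVM", "MB", "kNN", "LDA")) {
    pred <- run_cv(ds, classifier_spec(fam, n_tree = 200), folds)
    expect_gte(mean(pred$correct), 0.95)
  }
  for (fam in c("RF", "NN", "SVM")) {
    pred <- run_cv(ds, classifier_spec(fam, mode = "regression",
                                       n_tree = 200), folds)
    expect_gte(mean(pred$correct), 0.95)
    expect_true(all(pred$y_hat >= -0.3 & pred$y_hat <= 1.3))
  }
})

test_that("collect_confidence exposes the family-specific measure sets", {
  ds <- separable_blobs(n = 120, p = 6)
  folds <- kfold_split(120, 5, seed = 2, labels = ds$y)
  spec_rfr <- classifier_spec("RF", mode = "regression", n_tree = 100)
  cc <- collect_confidence(run_cv(ds, spec_rfr, folds), spec_rfr)
  expect_named(cc, c("class_lag", "std", "prob_std"))
  expect_true(all(cc$class_lag <= 0.5 + 1e-12))
  expect_true(all(cc$prob_std <= 0.5 + 1e-12))
  expect_true(all(as.matrix(cc) >= 0))

  spec_mb <- classifier_spec("MB", n_boost = 30, n_bag = 5)
  cc_mb <- collect_confidence(run_cv(ds, spec_mb, folds), spec_mb)
  expect_named(cc_mb, c("margin_error", "vote_error"))
  expect_true(all(as.matrix(cc_mb) >= 0))

  spec_lda <- classifier_spec("LDA")
  cc_lda <- collect_confidence(run_cv(ds, spec_lda, folds), spec_lda)
  expect_named(cc_lda, "p_hat_error")
  expect_true(all(cc_lda$p_hat_error <= 0.5 + 1e-12))
})

test_that("degenerate inputs are refused", {
  one_class <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(1L, 10),
                               "continuous")
  expect_error(fit_predict(classifier_spec("LDA"), one_class,
                           matrix(0, 1, 2)), "one class")
  expect_error(classifier_spec("kNN", mode = "regression"), "regression mode")
})

test_that("classifier specs round-trip through plain-text key/value files", {
  spec <- classifier_spec("SVM", cost = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_classifier_spec(spec, path)
  back <- read_classifier_spec(path)
  expect_equal(back[names(back) != "gamma"], spec[names(spec) != "gamma"])
  expect_null(back$gamma)
})
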