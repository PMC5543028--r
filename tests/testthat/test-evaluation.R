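test_that("roc_auc equals the Mann-Whitney pair-counting oracle", {
  expect_equal(roc_auc(c(5, 4, 3, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "one class")
  with_seed_local(91, {
    for (i in 1:10) {
      n <- sample(20:50, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
      positive <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(positive)) < 2) next
      expect_equal(roc_auc(scores, positive)$auc,
                   mann_whitney_auc(scores, positive))
    }
  })
})

test_that("roc_auc agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  with_seed_local(92, {
    scores <- c(rnorm(40, 1), rnorm(60))
    positive <- rep(c(TRUE, FALSE), c(40, 60))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(positive, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, positive)$auc, ref)
})

test_that("roc curve runs from (0,0) to (1,1) nondecreasingly", {
  with_seed_local(93, {
    cur <- roc_auc(rnorm(80), rep(c(TRUE, FALSE), 40))
  })
  expect_equal(cur$xs[1], 0)
  expect_equal(cur$ys[1], 0)
  expect_equal(cur$xs[length(cur$xs)], 1)
  expect_equal(cur$ys[length(cur$ys)], 1)
  expect_true(all(diff(cur$xs) >= 0) && all(diff(cur$ys) >= 0))
})

test_that("closed-form AUC bounds match the printed reference values", {
  expect_equal(auc_random(0.953, 0.955), 0.954)
  expect_equal(round_half_up(auc_max(0.953, 0.955), 3), 0.998)
  expect_equal(round_half_up(auc_random(0.823, 0.770), 3), 0.797)
  expect_equal(round_half_up(auc_max(0.823, 0.770), 3), 0.959)
  expect_equal(auc_random(1, 1), 1)
  expect_equal(auc_max(0.5, 0.5), 0.75)
  expect_error(auc_random(1.2, 0.5), "\\[0, 1\\]")
  expect_error(auc_max(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("signed-score construction attains the closed-form bounds", {
  # perfect classifier: separable by sign alone, any AD values
  perfect <- confusion_prediction_set(40, 0, 60, 0)
  expect_equal(roc_auc(ad_ranking_score(perfect, random_ad(100, 1)),
                       perfect$true_class == 1L)$auc, 1)
  # ideal AD ordering reproduces auc_max exactly (brute-force pair counting)
  for (sc in list(c(0.823, 0.770), c(0.953, 0.955), c(0.6, 0.9))) {
    ps <- confusion_prediction_set(round(1000 * sc[1]),
                                   round(1000 * (1 - sc[1])),
                                   round(1000 * sc[2]),
                                   round(1000 * (1 - sc[2])))
    s <- ad_ranking_score(ps, ideal_ad(ps))
    expect_equal(roc_auc(s, ps$true_class == 1L)$auc,
                 auc_max(sc[1], sc[2]), tolerance = 1e-12)
    expect_equal(mann_whitney_auc(s, ps$true_class == 1L),
                 auc_max(sc[1], sc[2]), tolerance = 1e-12)
  }
})

test_that("uninformative AD values center the AUC at auc_random", {
  ps <- confusion_prediction_set(82, 18, 77, 23)
  pt <- permutation_test_auc(ps, random_ad(200, 2), B = 400, seed = 6)
  expect_equal(pt$null_median, auc_random(0.82, 0.77), tolerance = 0.02)
  expect_gt(pt$p_value, 0.05)
})

test_that("permutation test gives the minimal p for an ideal AD measure", {
  ps <- confusion_prediction_set(80, 20, 70, 30)
  pt <- permutation_test_auc(ps, ideal_ad(ps), B = 199, seed = 4)
  expect_equal(pt$p_value, 1 / 200)
  expect_true(pt$significant)
  expect_error(permutation_test_auc(ps, ideal_ad(ps), B = 50), "99")
})

test_that("cumulative accuracy curve matches direct computation", {
  allgood <- confusion_prediction_set(5, 0, 5, 0)
  ca <- cumulative_accuracy_curve(allgood, random_ad(10, 3))
  expect_true(all(ca$ys == 1))

  ps <- confusion_prediction_set(3, 1, 0, 0)   # correctness 1,1,1,0
  # order by AD: correct, correct, error, correct
  ad <- c(1, 2, 4, 3)
  correct <- c(TRUE, TRUE, TRUE, FALSE)
  ps$correct <- correct
  ca2 <- cumulative_accuracy_curve(ps, ad, quantiles = c(0.5, 1))
  expect_equal(ca2$ys, c(1.0, 0.75))
})

test_that("flat cumulative accuracy under an uninformative AD measure", {
  ps <- confusion_prediction_set(400, 100, 350, 150)
  ca <- cumulative_accuracy_curve(ps, random_ad(1000, 9),
                                  quantiles = c(0.25, 0.5, 0.75, 1))
  acc <- mean(ps$correct)
  expect_true(all(abs(ca$ys - acc) < 3 * sqrt(acc * (1 - acc) / 250)))
})

test_that("predictiveness curve recovers bin error rates", {
  ps <- confusion_prediction_set(40, 10, 40, 10)
  ad <- ideal_ad(ps) + random_ad(100, 5) * 0.5   # errors strictly last
  pc <- predictiveness_curve(ps, ad, bins = 10)
  expect_equal(pc$ys[9:10], c(1, 1))             # 20 errors fill last 2 bins
  expect_true(all(pc$ys[1:8] == 0))
  expect_error(predictiveness_curve(ps, ad, bins = 200), "more bins")

  # error probability rising linearly with the AD rank
  n <- 5000
  ad_lin <- seq_len(n) / n
  p_err <- 0.4 * ad_lin
  correct <- with_seed_local(61, runif(n) > p_err)
  ps_lin <- structure(list(predicted_class = rep(1L, n), correct = correct,
                           true_class = rep(1L, n)),
                      class = "prediction_set")
  pc_lin <- predictiveness_curve(ps_lin, ad_lin, bins = 10)
  expected <- 0.4 * pc_lin$xs
  se <- sqrt(expected * (1 - expected) / (n / 10))
  expect_true(all(abs(pc_lin$ys - expected) <= 3 * pmax(se, 0.01)))
})

test_that("every benchmark criterion is invariant under monotone AD transforms", {
  ps <- confusion_prediction_set(60, 15, 50, 25)
  ad <- random_ad(150, 7)
  trans <- function(x) exp(3 * x) + 1          # strictly increasing
  s1 <- ad_ranking_score(ps, ad)
  s2 <- ad_ranking_score(ps, trans(ad))
  expect_equal(s1, s2)
  expect_equal(roc_auc(s1, ps$true_class == 1L)$auc,
               roc_auc(s2, ps$true_class == 1L)$auc)
  expect_equal(cumulative_accuracy_curve(ps, ad)$ys,
               cumulative_accuracy_curve(ps, trans(ad))$ys)
  expect_equal(predictiveness_curve(ps, ad)$ys,
               predictiveness_curve(ps, trans(ad))$ys)
  expect_equal(permutation_test_auc(ps, ad, B = 99, seed = 2)$p_value,
               permutation_test_auc(ps, trans(ad), B = 99, seed = 2)$p_value)
})

test_that("rank_measures averages per-dataset ranks with mean-rank ties", {
  one <- matrix(c(0.9, 0.8, 0.7), 3, 1,
                dimnames = list(c("a", "b", "c"), "d1"))
  rk <- rank_measures(one)
  expect_equal(rk$mean_rank, c(1, 2, 3))
  tied <- matrix(0.8, 2, 4, dimnames = list(c("a", "b"), paste0("d", 1:4)))
  expect_equal(rank_measures(tied)$mean_rank, c(1.5, 1.5))
  # rounding to two decimals precedes ranking
  close <- matrix(c(0.851, 0.849), 2, 1, dimnames = list(c("a", "b"), "d1"))
  expect_equal(rank_measures(close)$mean_rank, c(1.5, 1.5))
  expect_equal(rank_measures(close, round_digits = Inf)$mean_rank, c(1, 2))
  expect_error(rank_measures(matrix(c(1, NA), 2, 1)), "incomplete")
})
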