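test_that("F-score ranking matches hand evaluation and flags degenerate features", {
  x <- cbind(a = c(2, 4, 0, 2),      # hand case: F = 0.5
             b = c(1, 3, 1, 3),      # equal class means -> F = 0
             d = c(5, 5, 1, 1))      # constant within class -> flagged
  labels <- c("patient", "patient", "control", "control")
  rk <- f_score_rank(x, labels)
  expect_equal(rk$f[rk$feature == 1], 0.5)
  expect_equal(rk$f[rk$feature == 2], 0)
  expect_true(rk$flagged[rk$feature == 3])
  expect_equal(rk$feature[nrow(rk)], 3L)  # degenerate ranked last
  expect_equal(rk$feature[1], 1L)
  expect_error(f_score_rank(x, rep("patient", 4)), "both classes")
})

test_that("ROC AUC equals brute-force concordance and handles boundaries", {
  labels <- rep(c("patient", "control"), each = 4)
  expect_equal(roc_auc(c(2, 3, 4, 5, -1, -2, -3, -4), labels), 1)
  expect_equal(roc_auc(c(-1, -2, -3, -4, 2, 3, 4, 5), labels), 0)
  set.seed(181)
  for (rep in 1:20) {
    dv <- sample(seq(-1, 1, by = 0.25), 8, replace = TRUE)  # with ties
    expect_equal(roc_auc(dv, labels), brute_auc_roc(dv, labels),
                 tolerance = 1e-12)
  }
})

test_that("performance counts accuracy, sensitivity and specificity correctly", {
  labels <- rep(c("patient", "control"), c(28, 28))
  pred <- labels
  pred[1:4] <- "control"    # 24 of 28 patients correct
  pred[29:35] <- "patient"  # 21 of 28 controls correct
  dv <- ifelse(pred == "patient", 1, -1)
  pf <- performance(pred, dv, labels)
  expect_equal(pf$accuracy, 45 / 56)
  expect_equal(pf$sensitivity, 24 / 28)
  expect_equal(pf$specificity, 21 / 28)

  perfect <- performance(labels, ifelse(labels == "patient", 1, -1), labels)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, roc_auc = 1))
})

test_that("LOOCV separates Gaussian clouds and is chance-level on permuted labels", {
  gc <- gaussian_clouds(n_per_class = 20, n_features = 50,
                        n_informative = 10, d = 4, seed = 5)
  cv <- loocv_linear_svm(gc$x, gc$labels, n_features = 10,
                         c_grid = c(0.1, 1, 10), seed = 2)
  expect_gte(mean(cv$predictions == gc$labels), 0.95)
  expect_identical(cv$predictions,
                   loocv_linear_svm(gc$x, gc$labels, 10,
                                    c_grid = c(0.1, 1, 10),
                                    seed = 2)$predictions)

  accs <- vapply(1:20, function(s) {
    set.seed(s)
    small <- gaussian_clouds(n_per_class = 10, n_features = 20,
                             n_informative = 0, d = 0, seed = s)
    cvp <- loocv_linear_svm(small$x, sample(small$labels), 5, c_grid = 1,
                            seed = s)
    mean(cvp$predictions == cvp$labels)
  }, numeric(1))
  expect_true(all(accs >= 0.2 & accs <= 0.8))
  expect_lt(abs(mean(accs) - 0.5), 0.15)

  tiny <- gaussian_clouds(n_per_class = 1, n_features = 5)
  expect_error(loocv_linear_svm(tiny$x, tiny$labels, 2), ">= 2 subjects")
})

test_that("feature selection and scaling never see the held-out subject", {
  gc <- gaussian_clouds(n_per_class = 8, n_features = 15, n_informative = 5,
                        d = 2, seed = 9)
  cv <- loocv_linear_svm(gc$x, gc$labels, 5, c_grid = 1, seed = 3)
  x2 <- gc$x
  x2[4, ] <- x2[4, ] * 1e3 + 100  # corrupt the held-out row only
  cv2 <- loocv_linear_svm(x2, gc$labels, 5, c_grid = 1, seed = 3)
  expect_identical(cv$fold_features[[4]], cv2$fold_features[[4]])
  expect_identical(cv$fold_weights[[4]], cv2$fold_weights[[4]])
})

test_that("permutation p respects its boundaries and estimator", {
  gc <- gaussian_clouds(n_per_class = 4, n_features = 6, n_informative = 2,
                        d = 3, seed = 11)
  pt_hi <- permutation_test(gc$x, gc$labels, 3, observed_accuracy = 1.01,
                            B = 5, c_grid = 1, seed = 4)
  expect_equal(pt_hi$p, 1 / 6)
  pt_lo <- permutation_test(gc$x, gc$labels, 3, observed_accuracy = 0,
                            B = 5, c_grid = 1, seed = 4)
  expect_equal(pt_lo$p, 1)
  expect_length(pt_hi$permuted_accuracies, 5L)
  # monotone non-increasing in observed accuracy
  ps <- vapply(c(0, 0.5, 0.75, 1.01), function(obs)
    permutation_test(gc$x, gc$labels, 3, obs, B = 5, c_grid = 1,
                     seed = 4)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("consensus features, signs and weighted regions follow their definitions", {
  fe <- data.frame(feature = c("1_2", "1_3", "2_4"),
                   i = c(1L, 1L, 2L), j = c(2L, 3L, 4L))
  cv <- structure(list(
    fold_features = list(c("1_2", "1_3"), c("1_2", "1_3")),
    fold_weights = list(c("1_2" = 0.4, "1_3" = -0.2),
                        c("1_2" = 0.2, "1_3" = -0.2))),
    class = "loocv_svm")
  cw <- consensus_and_weights(cv, fe)
  expect_setequal(cw$consensus_features$feature, c("1_2", "1_3"))
  expect_equal(cw$consensus_features$mean_weight[
    cw$consensus_features$feature == "1_2"], 0.3)
  expect_equal(cw$consensus_features$sign[
    cw$consensus_features$feature == "1_3"], -1)
  # node 1 touches both consensus edges: weight 0.3 + 0.2 = 0.5
  rw <- cw$region_weights
  expect_equal(rw$weight[rw$node == 1], 0.5)
  expect_equal(rw$weight[rw$node == 2], 0.3)

  # degenerate: all region weights equal -> every touched node passes, flagged
  cv2 <- structure(list(
    fold_features = list("1_2"), fold_weights = list(c("1_2" = 0.4))),
    class = "loocv_svm")
  cw2 <- consensus_and_weights(cv2, fe)
  expect_true(cw2$degenerate)
  expect_setequal(cw2$weighted_regions, c(1L, 2L))

  # disjoint selections -> empty consensus reported, not an error
  cv3 <- structure(list(
    fold_features = list("1_2", "1_3"),
    fold_weights = list(c("1_2" = 1), c("1_3" = 1))),
    class = "loocv_svm")
  cw3 <- consensus_and_weights(cv3, fe)
  expect_equal(nrow(cw3$consensus_features), 0L)
})

test_that("feature-count search maximizes accuracy with ties to the smaller count", {
  gc <- gaussian_clouds(n_per_class = 8, n_features = 12, n_informative = 3,
                        d = 5, seed = 13)
  fs1 <- feature_count_search(gc$x, gc$labels, candidates = 4, c_grid = 1)
  expect_equal(fs1$best_n, 4L)

  fs <- feature_count_search(gc$x, gc$labels, candidates = c(3, 6),
                             c_grid = 1, seed = 5)
  # strongly separable either way: both counts reach the same accuracy,
  # so the tie rule must return the smaller count
  if (fs$accuracies[1] == fs$accuracies[2])
    expect_equal(fs$best_n, 3L)
  expect_equal(fs$best_n,
               as.integer(names(which.max(fs$accuracies))))

  expect_error(feature_count_search(gc$x, gc$labels, integer(0)),
               "empty")

  # informative features concentrated in the top ranks: richer selection
  # should not hurt, in the majority of seeds
  wins <- vapply(1:10, function(s) {
    g2 <- gaussian_clouds(n_per_class = 8, n_features = 20,
                          n_informative = 10, d = 1.5, seed = 100 + s)
    f2 <- feature_count_search(g2$x, g2$labels, candidates = c(2, 10),
                               c_grid = 1, seed = s)
    f2$accuracies["10"] >= f2$accuracies["2"]
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})
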