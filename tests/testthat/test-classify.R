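make_xy <- function(n_f = 12, n_m = 18, p = 4, sep = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_f * p), n_f),
             matrix(rnorm(n_m * p, mean = sep), n_m))
  y <- rep(c("female", "male"), c(n_f, n_m))
  list(X = X, y = y)
}

test_that("SMOTE balances 12/18 and synthesizes on minority segments", {
  d <- make_xy()
  out <- smote_oversample(d$X, d$y, "balance", seed = 5)
  expect_identical(as.integer(table(out$y)), c(18L, 18L))
  syn <- out$X[31:36, , drop = FALSE]
  Xm <- d$X[1:12, ]
  for (i in seq_len(nrow(syn))) {
    # distance from the synthetic point to its nearest minority segment
    dmin <- min(apply(utils::combn(12, 2), 2, function(pr) {
      a <- Xm[pr[1], ]; b <- Xm[pr[2], ]
      ab <- b - a
      t <- sum((syn[i, ] - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      sqrt(sum((syn[i, ] - (a + t * ab))^2))
    }))
    expect_lt(dmin, 1e-9)
  }
})

test_that("SMOTE respects percent = 0, determinism, and tiny minorities", {
  d <- make_xy()
  same <- smote_oversample(d$X, d$y, 0)
  expect_identical(same$X, d$X)
  a <- smote_oversample(d$X, d$y, 100, seed = 3)
  b <- smote_oversample(d$X, d$y, 100, seed = 3)
  expect_identical(a$X, b$X)
  expect_identical(nrow(a$X), 42L)    # +100% of 12 minority
  X1 <- rbind(c(0, 0), c(5, 5), c(5, 6))
  expect_error(smote_oversample(X1, c("female", "male", "male"), "balance"),
               "fewer than 2")
})

test_that("kNN votes match hand geometry and the brute-force oracle", {
  tr_X <- rbind(matrix(0, 4, 2), matrix(10, 6, 2))
  tr_y <- rep(c("female", "male"), c(4, 6))
  out <- knn_classify(tr_X, tr_y, matrix(c(1, 1), 1), k = 7)
  expect_identical(as.character(out$labels), "female")
  expect_equal(out$scores, 4 / 7)

  exact <- knn_classify(tr_X, tr_y, tr_X[5, , drop = FALSE], k = 1)
  expect_identical(as.character(exact$labels), "male")
  expect_identical(exact$scores, 0)

  set.seed(61)
  for (r in 1:50) {
    d <- make_xy(n_f = 8, n_m = 10, p = 3, sep = 0.5, seed = r)
    te <- matrix(rnorm(15), 5, 3)
    k <- sample(c(1, 3, 7), 1)
    expect_equal(knn_classify(d$X, d$y, te, k)$scores,
                 knn_brute(d$X, d$y, te, k))
  }
  expect_error(knn_classify(tr_X[1:3, ], tr_y[1:3], tr_X, k = 7), "exceeds")
})

test_that("RBF SVM separates a wide-margin toy and satisfies the dual", {
  set.seed(71)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 5, 0.1), 10, 2))
  y <- rep(c("female", "male"), each = 10)
  out <- svm_rbf(X, y, X, C = 10, sigma = 0.5)
  expect_identical(as.character(out$labels), y)
  expect_true(all(out$scores[1:10] > 0))
  expect_true(all(out$scores[11:20] < 0))
  coefs <- out$model$coefs[, 1]
  expect_true(all(abs(coefs) <= 10 + 1e-6))        # dual box 0 <= alpha <= C
  expect_lt(abs(sum(coefs)), 1e-6)                 # sum alpha_i y_i = 0
  expect_error(svm_rbf(X[1:10, ], y[1:10], X), "single class")
})

test_that("SVM decision values agree with a QP oracle on a toy problem", {
  set.seed(73)
  X <- rbind(matrix(rnorm(20, 0, 0.6), 10, 2),
             matrix(rnorm(20, 2.5, 0.6), 10, 2))
  y <- rep(c("female", "male"), each = 10)
  te <- matrix(rnorm(24, 1.2, 1.5), 12, 2)
  out <- svm_rbf(X, y, te, C = 10, sigma = 1)
  y_pm <- ifelse(y == "female", 1, -1)
  oracle <- svm_decision_oracle(X, y_pm, te, C = 10, sigma = 1)
  expect_equal(cor(out$scores, oracle, method = "spearman"), 1,
               tolerance = 1e-9)
  expect_gt(cor(out$scores, oracle), 0.999)
})

test_that("confusion matrix uses row percentages", {
  y_true <- c("female", "female", "female", "male")
  y_pred <- c("female", "female", "male", "male")
  cm <- confusion_matrix_pct(y_true, y_pred)
  expect_equal(unname(cm), rbind(c(200 / 3, 100 / 3), c(0, 100)))
  perfect <- confusion_matrix_pct(y_true, y_true)
  expect_equal(unname(perfect), 100 * diag(2))
  set.seed(3)
  yt <- sample(c("female", "male"), 40, replace = TRUE)
  yp <- sample(c("female", "male"), 40, replace = TRUE)
  expect_equal(unname(rowSums(confusion_matrix_pct(yt, yp))), c(100, 100))
  cm_na <- confusion_matrix_pct(rep("male", 4), sample(c("female", "male"), 4,
                                                       replace = TRUE))
  expect_true(all(is.na(cm_na["female", ])))
})

test_that("ROC/AUC equal the pairwise U-statistic oracle", {
  y <- rep(c("female", "male"), c(3, 3))
  perfect <- roc_auc(y, c(3, 2.5, 2, 1, 0.5, 0))
  expect_equal(perfect$auc, 1)
  flat <- roc_auc(y, rep(1, 6))
  expect_equal(flat$auc, 0.5)
  set.seed(81)
  for (r in 1:50) {
    n <- sample(6:20, 1)
    y <- sample(rep(c("female", "male"), c(ceiling(n / 2), floor(n / 2))))
    s <- sample(round(rnorm(n), 1))          # ties likely
    out <- roc_auc(y, s)
    expect_equal(out$auc, auc_brute(y, s), tolerance = 1e-12)
    expect_true(all(diff(out$roc_points$fpr) >= 0))
    expect_true(all(diff(out$roc_points$tpr) >= -1e-12))
    expect_equal(unlist(out$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(out$roc_points[nrow(out$roc_points), ]),
                 c(fpr = 1, tpr = 1))
  }
})

test_that("cross-validation is deterministic and exact on separable data", {
  d <- make_xy(sep = 8, seed = 5)
  cfg <- classifier_config("knn", seed = 17)
  r1 <- cross_validate_grid(d$X, d$y, cfg)
  r2 <- cross_validate_grid(d$X, d$y, cfg)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_equal(r1$accuracy, 100)
  expect_equal(r1$auc, 1)
  expect_equal(max(abs(r1$confusion_pct - 100 * diag(2))), 0)

  rs <- cross_validate_grid(d$X, d$y,
                            classifier_config("svm", C_grid = 10,
                                              sigma_grid = 0.5, seed = 17))
  expect_equal(rs$accuracy, 100)
  expect_equal(rs$auc, 1)
})

test_that("report accuracy is consistent with pooled confusion counts", {
  d <- make_xy(sep = 1, seed = 9)
  r <- cross_validate_grid(d$X, d$y, classifier_config("knn", seed = 2))
  n_f <- sum(d$y == "female"); n_m <- sum(d$y == "male")
  pooled <- (r$confusion_pct[1, 1] * n_f + r$confusion_pct[2, 2] * n_m) /
    (n_f + n_m)
  expect_equal(pooled, r$accuracy_pooled, tolerance = 1e-9)
})

test_that("a shuffled label-copy feature cannot beat chance (no leakage)", {
  set.seed(91)
  d <- make_xy(n_f = 12, n_m = 18, p = 10, sep = 0)
  canary <- sample(as.numeric(factor(d$y)))   # label values, shuffled
  X <- cbind(canary, d$X)
  acc <- cross_validate_grid(X, d$y, classifier_config("knn", seed = 3))$accuracy
  expect_gt(acc, 25)
  expect_lt(acc, 75)
})

test_that("stratification failure is reported", {
  d <- make_xy(n_f = 3, n_m = 18)
  expect_error(
    cross_validate_grid(d$X, d$y, classifier_config("knn", folds = 10,
                                                    seed = 1)),
    "stratification")
})

test_that("grid search selects sane hyperparameters via inner CV", {
  d <- make_xy(sep = 3, seed = 13)
  cfg <- classifier_config("svm", C_grid = c(0.01, 10),
                           sigma_grid = c(0.5, 1), folds = 5,
                           inner_folds = 3, seed = 11)
  r <- cross_validate_grid(d$X, d$y, cfg)
  expect_length(r$best_params, 5)
  expect_true(all(vapply(r$best_params, function(p)
    p$C %in% c(0.01, 10) && p$sigma %in% c(0.5, 1), logical(1))))
  expect_gt(r$accuracy, 85)
})

test_that("classification difficulty rises with the group Hurst contrast", {
  acc_dh <- function(seed, dh) {
    cfg <- make_tiny_cohort(
      seed = seed, n_channels = 4,
      hurst_by_group = list(female = 0.66 - dh / 2, male = 0.66 + dh / 2),
      mix_p_by_group = list(female = 0.35, male = 0.35))
    segs <- do.call(c, lapply(generate_cohort(cfg), segment_recording))
    ft <- build_feature_table(segs, layout = "HUR")
    cross_validate_grid(ft$matrix, ft$labels,
                        classifier_config("knn", seed = seed))$accuracy
  }
  seeds <- 1:5
  acc0 <- mean(vapply(seeds, acc_dh, numeric(1), dh = 0))
  acc2 <- mean(vapply(seeds, acc_dh, numeric(1), dh = 0.2))
  expect_gt(acc2, acc0)
  expect_gt(acc2, 90)
})
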