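test_that("roc_auc matches hand-enumerated cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  # exhaustive pair enumeration: all 4 (pos, neg) pairs concordant
  expect_equal(roc_auc(c(0.2, 0.6, 0.4, 0.8), c(0, 1, 0, 1))$auc, 1)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(1)
  s <- runif(200); y <- rbinom(200, 1, s)
  a1 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(qlogis(s), y)$auc, a1)
  expect_equal(roc_auc(s^3 + 10, y)$auc, a1)
})

test_that("the ROC step curve starts at (0,0) and ends at (1,1)", {
  set.seed(2)
  s <- runif(100); y <- rbinom(100, 1, 0.4)
  r <- roc_auc(s, y)
  expect_equal(unlist(r$roc[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(r$roc[nrow(r$roc), c("fpr", "tpr")],
                      use.names = FALSE), c(1, 1))
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  path <- tempfile(fileext = ".tsv")
  write_roc_points(r, path)
  expect_equal(names(read.delim(path)), c("fpr", "tpr", "threshold"))
  unlink(path)
})

test_that("cv_predictions share folds across learners and are out-of-fold", {
  set.seed(3)
  n <- 200
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 1))
  sl <- cv_predictions(X, y, "super_learner", V = 5, seed = 11,
                       sl_library = c("GLM", "MEAN"))
  sw <- cv_predictions(X, y, "stepwise", V = 5, seed = 11)
  expect_identical(sl$folds, sw$folds)
  expect_false(any(is.na(sl$pred)))

  # MEAN-only learner: constant prediction within each fold
  mo <- cv_predictions(X, y, "super_learner", V = 5, seed = 11,
                       sl_library = "MEAN")
  for (v in 1:5)
    expect_equal(length(unique(mo$pred[mo$folds == v])), 1L)
})

test_that("signal-free outcomes give chance-level cross-validated AUC", {
  set.seed(4)
  n <- 600
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- rbinom(n, 1, 0.5)
  cvp <- cv_predictions(X, y, "stepwise", V = 5, seed = 12)
  a <- roc_auc(cvp$pred, y)$auc
  # null AUC standard error is roughly 1 / sqrt(3 * min(n1, n0))
  expect_lt(abs(a - 0.5), 3 / sqrt(3 * min(sum(y), sum(1 - y))))
})

test_that("super learner is not outperformed by stepwise on a strong signal", {
  set.seed(5)
  n <- 800
  X <- cbind(x1 = runif(n), x2 = runif(n), x3 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(3 * sin(3 * X[, 1]) + 2 * X[, 3] - 1))
  sl <- cv_predictions(X, y, "super_learner", V = 5, seed = 13,
                       sl_library = c("GLM", "GAM", "MEAN"))
  sw <- cv_predictions(X, y, "stepwise", V = 5, seed = 13)
  auc_sl <- roc_auc(sl$pred, y)$auc
  auc_sw <- roc_auc(sw$pred, y)$auc
  expect_gte(auc_sl, auc_sw - 0.01)
})
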