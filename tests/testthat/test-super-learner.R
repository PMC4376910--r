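test_that("MEAN-only library puts weight 1 on MEAN and predicts the proportion", {
  set.seed(1)
  X <- matrix(runif(120), ncol = 2)
  y <- rbinom(60, 1, 0.3)
  fit <- sl_fit(X, y, library = "MEAN", V = 5, seed = 1)
  expect_equal(unname(fit$weights), 1)
  p <- predict(fit, X)
  expect_true(all(abs(p - mean(y)) < 1e-12))
})

test_that("weights lie on the simplex and predictions are convex combinations", {
  set.seed(2)
  X <- matrix(runif(400), ncol = 2)
  y <- rbinom(200, 1, plogis(2 * X[, 1] - 1))
  fit <- sl_fit(X, y, library = c("GLM", "BGLM", "MEAN"), V = 5, seed = 2)
  expect_true(all(fit$weights >= -1e-12))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)

  Xn <- matrix(runif(60), ncol = 2)
  cand_preds <- sapply(fit$library, function(nm)
    shiftvim:::.sl_candidates[[nm]]$predict(fit$candidates[[nm]],
                                            shiftvim:::as_learner_frame(Xn)))
  p <- predict(fit, Xn)
  expect_true(all(p >= apply(cand_preds, 1, min) - 1e-6))
  expect_true(all(p <= apply(cand_preds, 1, max) + 1e-6))
})

test_that("GLM dominates when the truth is main-terms logistic", {
  set.seed(3)
  n <- 2000
  X <- cbind(x1 = runif(n), x2 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * X[, 1] - X[, 2]))
  fit <- sl_fit(X, y, library = c("GLM", "MEAN"), V = 10, seed = 3)
  expect_gt(fit$weights[["GLM"]], 0.9)
  # finite-sample oracle property: ensemble CV risk near the best candidate
  expect_lte(fit$cv_risks[["ensemble"]],
             min(fit$cv_risks[fit$library]) * 1.02 + 1e-8)
})

test_that("full six-candidate library fits and is seed-deterministic", {
  set.seed(4)
  n <- 300
  X <- cbind(x1 = runif(n), x2 = runif(n), x3 = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(sin(3 * X[, 1]) + X[, 3] - 0.5))
  f1 <- sl_fit(X, y, V = 5, seed = 11)
  f2 <- sl_fit(X, y, V = 5, seed = 11)
  expect_identical(f1$weights, f2$weights)
  expect_setequal(names(f1$weights),
                  c("GLM", "SW", "BGLM", "GAM", "MARS", "MEAN"))
  expect_lte(f1$cv_risks[["ensemble"]], min(f1$cv_risks[f1$library]) + 1e-8)
  p <- predict(f1, X)
  expect_true(all(p > 0 & p < 1))
})

test_that("degenerate outcome falls back to MEAN with a warning", {
  X <- matrix(runif(60), ncol = 2)
  expect_warning(fit <- sl_fit(X, rep(0, 30), library = c("GLM", "MEAN"),
                               V = 5, seed = 1),
                 "degenerate")
  expect_equal(fit$library, "MEAN")
})

test_that("prediction rejects mismatched columns", {
  X <- matrix(runif(100), ncol = 2)
  y <- rbinom(50, 1, 0.5)
  fit <- sl_fit(X, y, library = "GLM", V = 5, seed = 1)
  expect_error(predict(fit, matrix(runif(30), ncol = 3)), "columns")
})

test_that("the diagnostic report has the candidate/cv_risk/weight layout", {
  set.seed(5)
  X <- matrix(runif(200), ncol = 2)
  y <- rbinom(100, 1, 0.4)
  fit <- sl_fit(X, y, library = c("GLM", "MEAN"), V = 5, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_sl_report(fit, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("candidate", "cv_risk", "weight"))
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-8)
  unlink(path)
})
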