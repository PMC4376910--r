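test_that("uniform exposure yields a near-flat estimated density", {
  set.seed(1)
  n <- 5000
  A <- runif(n)
  W <- matrix(rbinom(n, 1, 0.5), dimnames = list(NULL, "w"))
  g <- density_fit(A, W, candidates = expand.grid(
    n_bins = c(2L, 5L, 10L), placement = "equal_width",
    stringsAsFactors = FALSE), V = 5, seed = 1)
  grid <- seq(0.01, 0.99, length.out = 50)
  for (w in c(0, 1)) {
    vals <- density_eval(g, grid, matrix(w, length(grid), 1))
    expect_true(all(vals > 0.8 & vals < 1.2))
  }
})

test_that("a single 1-bin candidate gives the uniform density", {
  set.seed(2)
  A <- rbeta(200, 2, 2)
  W <- matrix(runif(200))
  g <- density_fit(A, W, candidates = data.frame(n_bins = 1L,
                                                 placement = "equal_width"),
                   V = 5, seed = 2)
  a <- c(0.05, 0.33, 0.91)
  expect_equal(density_eval(g, a, matrix(0.5, 3, 1)), rep(1, 3))
})

test_that("density is piecewise constant, nonnegative, zero off-support", {
  set.seed(3)
  A <- rbeta(500, 2, 5)
  W <- matrix(rbinom(500, 1, 0.5))
  g <- density_fit(A, W, candidates = data.frame(n_bins = 5L,
                                                 placement = "equal_width"),
                   V = 5, seed = 3)
  w <- matrix(1, 2, 1)
  # same bin (width 0.2), same w -> identical values
  expect_equal(density_eval(g, c(0.41, 0.55), w)[1],
               density_eval(g, c(0.41, 0.55), w)[2])
  expect_equal(density_eval(g, c(-0.05, 1.05), w), c(0, 0))
  expect_true(all(density_eval(g, seq(0, 1, 0.05), matrix(0, 21, 1)) >= 0))
})

test_that("density integrates to one at every covariate value", {
  set.seed(4)
  n <- 800
  W <- matrix(runif(n), dimnames = list(NULL, "w"))
  A <- pmin(pmax(rbeta(n, 2, 2) * 0.5 + 0.3 * W[, 1], 1e-3), 1 - 1e-3)
  g <- density_fit(A, W, candidates = expand.grid(
    n_bins = c(4L, 8L), placement = c("equal_width", "equal_frequency"),
    stringsAsFactors = FALSE), V = 5, seed = 4)
  for (w in c(0.1, 0.5, 0.9)) {
    int <- stats::integrate(function(a)
      density_eval(g, a, matrix(w, length(a), 1)), 0, 1,
      subdivisions = 2000L, rel.tol = 1e-9)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
})

test_that("the stack is no worse than the best single candidate in CV log-lik", {
  set.seed(5)
  n <- 1200
  W <- matrix(rbinom(n, 1, 0.5), dimnames = list(NULL, "w"))
  A <- ifelse(W[, 1] == 1, rbeta(n, 5, 2), rbeta(n, 2, 5))
  g <- density_fit(A, W, candidates = expand.grid(
    n_bins = c(2L, 5L, 10L), placement = "equal_width",
    stringsAsFactors = FALSE), V = 5, seed = 5)
  expect_gte(max(g$weights), 0)
  expect_equal(sum(g$weights), 1, tolerance = 1e-8)
  expect_gte(g$cv_loglik[["ensemble"]], max(g$cv_loglik[-length(g$cv_loglik)]) - 1e-6)
})

test_that("candidates with more bins than observations are dropped", {
  set.seed(6)
  A <- runif(15)
  W <- matrix(1, 15, 1)
  expect_warning(
    g <- density_fit(A, W, candidates = expand.grid(
      n_bins = c(2L, 20L), placement = "equal_width",
      stringsAsFactors = FALSE), V = 3, seed = 6),
    "dropped")
  expect_equal(length(g$candidates), 1L)
})
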