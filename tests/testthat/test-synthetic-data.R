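test_that("zero missingness strength gives fully observed data before death", {
  d <- generate_longitudinal(dgp_spec(n = 300, J = 3, K = 2,
                                      miss_strength = 0, seed = 1))
  alive_rows <- !is.na(d$death)  # n x J alive-at-interval indicator
  for (k in seq_len(d$K))
    expect_true(all(d$miss_flags[, , k][alive_rows] == 1))
})

test_that("with no covariate effects the death rate matches the intercept", {
  p0 <- 0.12
  spec <- dgp_spec(n = 2e4, J = 1, K = 2, miss_strength = 0,
                   conf_strength = 0, haz_intercept = qlogis(p0),
                   haz_coef = c(0, 0), haz_miss = 0, seed = 2)
  d <- generate_longitudinal(spec)
  rate <- mean(d$death[, 1])
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / 2e4))
})

test_that("the generator is Markov: L_j independent of L_{j-2} given history", {
  spec <- dgp_spec(n = 5e4, J = 3, K = 1, miss_strength = 0,
                   haz_intercept = qlogis(0.01), haz_coef = 0, haz_miss = 0,
                   conf_strength = 1, seed = 3)
  d <- generate_longitudinal(spec)
  alive <- rowSums(d$death == 1, na.rm = TRUE) == 0
  L1 <- d$covariates[alive, 1, 1]
  L2 <- d$covariates[alive, 2, 1]
  L3 <- d$covariates[alive, 3, 1]
  L0 <- d$baseline[alive, ]
  fit <- lm(L3 ~ L2 + L1 + L0)
  tval <- summary(fit)$coefficients["L1", "t value"]
  expect_lt(abs(tval), 3)
})

test_that("generated studies satisfy all data-model invariants and determinism", {
  s <- dgp_spec(n = 200, J = 2, K = 3, seed = 4)
  d1 <- generate_longitudinal(s)
  d2 <- generate_longitudinal(s)
  expect_identical(d1, d2)
  expect_s3_class(d1, "longitudinal_data")
  cont <- which(d1$var_meta$kind == "continuous")
  for (k in cont) {
    v <- d1$covariates[, , k]
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  }
  expect_true(is_binary_ok <- all(d1$covariates[, , 3] %in% c(0, 1, NA)))
})

test_that("worked example has the documented marginal structure", {
  cs <- generate_worked_example(2e4, "worked_logistic", seed = 5,
                                exposure = "continuous")
  A1 <- cs$A; A2 <- cs$W[, 1]
  expect_true(all(A1 >= 0.1 & A1 <= 0.9))
  expect_lt(abs(mean(A1) - 0.5), 0.01)
  expect_lt(abs(mean(A2) - 0.5), 0.01)
  expect_lt(abs(mean(cs$Y) - mean(plogis(A1 + A2))), 0.01)
  # binary view swaps the roles
  csb <- generate_worked_example(500, "worked_logistic", seed = 5,
                                 exposure = "binary")
  expect_equal(csb$exposure_kind, "binary")
  expect_true(is.numeric(csb$W[, "A1"]))
})

test_that("true_psi: linear scenario equals delta for both parameters", {
  for (dl in c(0.01, 0.05, 0.09)) {
    expect_equal(true_psi("worked_linear", "psi_c", dl), dl, tolerance = 1e-10)
    expect_equal(true_psi("worked_linear", "psi_b", dl), dl, tolerance = 1e-10)
  }
  expect_error(true_psi("worked_linear", "psi_b", 0.2), "positivity")
})

test_that("true_psi: Monte Carlo and quadrature agree", {
  for (tg in c("psi_c", "psi_b")) {
    q <- true_psi("worked_logistic", tg, 0.01)
    m <- true_psi("worked_logistic", tg, 0.01, method = "mc", n_mc = 1e6,
                  seed = 6)
    expect_lt(abs(q - m), 2e-5)
  }
  qc <- true_psi("confounded", "psi_b", 0.05)
  mc <- true_psi("confounded", "psi_b", 0.05, method = "mc", n_mc = 1e6,
                 seed = 7)
  expect_lt(abs(qc - mc), 2e-4)
})

test_that("confounded scenario marginals match the mechanism truths", {
  cs <- generate_confounded(4e4, seed = 8)
  # E[phi0(W1)] by quadrature over Uniform(0,1)
  ephi <- integrate(function(w) plogis(1.6 - 2.2 * 4 * (w - 0.5)^2), 0, 1,
                    rel.tol = 1e-10)$value
  expect_lt(abs(mean(cs$C) - ephi), 0.01)
  eg <- integrate(function(w) plogis(-1 + 2 * 4 * (w - 0.5)^2), 0, 1,
                  rel.tol = 1e-10)$value
  expect_lt(abs(mean(cs$A[cs$C == 1]) - eg), 0.015)
})

test_that("right and wrong confounded nuisance fits behave as designed", {
  cs <- generate_confounded(8000, seed = 9)
  right <- confounded_nuisances(cs, TRUE, TRUE, TRUE)
  wrong <- confounded_nuisances(cs, FALSE, FALSE, FALSE)
  W <- cs$W
  z1 <- 4 * (W[, 1] - 0.5)^2
  phitrue <- plogis(1.6 - 2.2 * z1)
  # correctly specified fit recovers the truth; main-terms fit cannot
  expect_lt(mean(abs(right$phi(W) - phitrue)), 0.01)
  expect_gt(mean(abs(wrong$phi(W) - phitrue)), 0.05)
})
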