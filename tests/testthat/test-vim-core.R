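test_that("clever covariate has its defining limiting values", {
  # uniform density, no missingness
  nu <- nuisance_set(qbar = function(a, W) rep(0.5, nrow(as.matrix(W))),
                     g = function(a, W) rep(1, nrow(as.matrix(W))),
                     kind = "continuous")
  W <- matrix(0.5, 3, 1)
  # delta = 0: H = 1 where observed (interior of the support)
  H0 <- clever_covariate(nu, delta = 1e-12)
  expect_equal(H0(c(0.3, 0.5, 0.7), c(1, 1, 1), W), rep(1, 3))
  # c = 0 -> H = 0
  expect_equal(H0(0.5, c(0, 0, 0), W), rep(0, 3))
  # uniform g, delta = 0.1, a = 0.5, phi = 1 -> ratio of a uniform = 1
  H1 <- clever_covariate(nu, delta = 0.1)
  expect_equal(H1(0.5, 1, W[1, , drop = FALSE]), 1)
})

test_that("positivity diagnostics flag low phi and respect clean setups", {
  cs <- generate_worked_example(500, "worked_logistic", seed = 1,
                                exposure = "binary")
  nu <- worked_example_nuisances("worked_logistic", "binary")
  rep1 <- positivity_check(nu, cs, delta = 0.01)
  expect_equal(rep1$n_phi_flagged, 0L)
  expect_true(rep1$delta_bound_ok)

  low_phi <- nuisance_set(qbar = nu$qbar, g = nu$g,
                          phi = function(W) rep(0.005, nrow(as.matrix(W))),
                          kind = "binary")
  rep2 <- positivity_check(low_phi, cs, delta = 0.01)
  expect_equal(rep2$n_phi_flagged, cs$n)
})

test_that("plug-in with true nuisances matches the quadrature oracle", {
  cs <- generate_worked_example(5e4, "worked_logistic", seed = 2,
                                exposure = "continuous")
  nu <- worked_example_nuisances("worked_logistic", "continuous")
  psi <- plug_in_psi_c(nu, cs, 0.01, ctl_fast)
  truth <- true_psi("worked_logistic", "psi_c", 0.01)
  # plug-in at true nuisances = truth + mean(m(W_i) - Y_i) sampling error;
  # sd(m - Y) <= 0.5 for a Bernoulli outcome, so bound at 3 * 0.5 / sqrt(n)
  tol <- 3 * 0.5 / sqrt(cs$n)
  expect_lt(abs(psi - truth), tol)

  csb <- generate_worked_example(5e4, "worked_logistic", seed = 2,
                                 exposure = "binary")
  nub <- worked_example_nuisances("worked_logistic", "binary")
  psib <- plug_in_psi_b(nub, csb, 0.01)
  expect_lt(abs(psib - true_psi("worked_logistic", "psi_b", 0.01)), tol)
})

test_that("binary delta bound is enforced strictly", {
  csb <- generate_worked_example(400, "worked_logistic", seed = 3,
                                 exposure = "binary")
  nub <- worked_example_nuisances("worked_logistic", "binary")
  # min g(0|1,w) = 1 - max(A1) ~= 0.1
  expect_error(plug_in_psi_b(nub, csb, 0.5), "positivity")
})

test_that("comparability: psi_c(delta)/delta approaches the derivative term", {
  # (Psi_c(delta) - Psi_c(0)) / delta -> E[d/da Qbar(a, W)] as delta -> 0;
  # at delta = 1e-4 the finite difference matches to 3 significant figures
  fd <- true_psi("worked_logistic", "psi_c", 1e-4) / 1e-4
  deriv <- stats::integrate(function(a) {
    f <- stats::dbeta((a - 0.1) / 0.8, 2, 2) / 0.8
    d1 <- stats::dlogis(stats::qlogis(stats::plogis(a)))      # expit'(a)
    d2 <- stats::dlogis(stats::qlogis(stats::plogis(a + 1)))  # expit'(a+1)
    f * ((1 - a) * d1 + a * d2)
  }, 0.1, 0.9, rel.tol = 1e-10)$value
  expect_equal(signif(fd, 3), signif(deriv, 3))
})

test_that("EE solution matches a pencil-and-paper evaluation (binary, n = 2)", {
  # phi = 1, C = 1, g(1|w) = 0.5, delta = 0.1, tabulated Qbar
  W <- matrix(c(0, 1), dimnames = list(NULL, "w"))
  cs <- cross_section(W = W, C = c(1, 1), A = c(1, 0), Y = c(1, 0),
                      exposure_kind = "binary")
  q <- function(a, W) ifelse(rep_len(a, 2) == 1, c(0.8, 0.6), c(0.4, 0.2))
  nu <- nuisance_set(qbar = q, g = function(W) rep(0.5, nrow(W)),
                     kind = "binary")
  est <- vim_ee(cs, nu, delta = 0.1)
  # by hand: obs 1 (w=0, A=1, Y=1): gA=.5, g*A=.6, qA=.8
  #   D+psi = 1.2*(1-.8) + .8 - (.5*.8+.5*.4) + m_b - 1,
  #   m_b = .6*.8+.4*.4 = .64 -> contribution = .24 + .2 + .64 - 1 = 0.08
  # obs 2 (w=1, A=0, Y=0): gA=.5, g*A=.4, qA=.2
  #   D+psi = 0.8*(0-.2) + .2 - (.5*.6+.5*.2) + m_b - 0,
  #   m_b = .6*.6+.4*.2 = .44 -> contribution = -.16 - .2 + .44 = 0.08
  expect_equal(est$psi, 0.08, tolerance = 1e-12)
})

test_that("eif_values is mean-zero at the EE solution and near-zero at truth", {
  cs <- generate_worked_example(2e4, "worked_logistic", seed = 4,
                                exposure = "continuous")
  nu <- worked_example_nuisances("worked_logistic", "continuous")
  ee <- vim_ee(cs, nu, 0.01, control = ctl_fast)
  ev <- eif_values(nu, cs, 0.01, psi = ee$psi, control = ctl_fast)
  expect_lt(abs(mean(ev$D)), 1e-10)
  # at the true parameter the EIF mean is O_p(n^{-1/2})
  ev0 <- eif_values(nu, cs, 0.01, psi = true_psi("worked_logistic", "psi_c", 0.01),
                    control = ctl_fast)
  expect_lt(abs(mean(ev0$D)), 3 * sd(ev0$D) / sqrt(cs$n))
})
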