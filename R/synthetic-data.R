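# Synthetic data with the statistical structure the method assumes: a
# structural equation system generating baseline covariates, Markov
# longitudinal covariates with informative missingness, and a discrete-time
# death hazard; plus two small worked-example generators (used to study
# comparability of the continuous and binary parameters) and a confounded
# cross-sectional scenario powering the double-robustness experiments.
# Every scenario has a brute-force oracle for its true parameter value
# (true_psi), independent of all estimation code.

#' Specification of the longitudinal data-generating process
#'
#' Structural functions are logistic-linear with the coefficients below;
#' continuous covariates are drawn from Beta distributions scaled into
#' (0,1), so the unit-interval convention holds without rescaling.
#' Missingness of a covariate depends on the previous time point's value,
#' the previous missingness indicator and baseline (informative
#' missingness); covariates are Markov given the previous time point and
#' baseline; the death hazard depends on current covariates, current
#' missingness and baseline, and death is absorbing.
#'
#' @param n subjects.
#' @param J number of measurement time points.
#' @param K number of longitudinal variables (the last one is binary, the
#'   rest continuous).
#' @param miss_strength in \[0,1\]: 0 gives fully observed data; the
#'   probability of missingness is `miss_strength * plogis(linear predictor)`.
#' @param conf_strength scales the baseline -> covariate and covariate ->
#'   hazard coefficients (confounding).
#' @param haz_intercept hazard intercept on the logit scale; with all other
#'   hazard coefficients zero the per-interval death rate is
#'   `plogis(haz_intercept)`.
#' @param haz_coef per-variable hazard log-odds coefficients (length K).
#' @param haz_miss hazard coefficient on the number of missing covariates
#'   (informative missingness).
#' @param times measurement times (default 0, 1, ..., J-1).
#' @param seed integer seed.
#' @return List of class `"dgp_spec"`.
#' @export
dgp_spec <- function(n = 500L, J = 3L, K = 3L, miss_strength = 0.3,
                     conf_strength = 1, haz_intercept = stats::qlogis(0.08),
                     haz_coef = c(1, rep(0.5, max(K - 1L, 0L)))[seq_len(K)],
                     haz_miss = 0.5, times = seq_len(J) - 1, seed = NULL) {
  stopifnot(n >= 2, J >= 1, K >= 1, miss_strength >= 0, miss_strength <= 1,
            length(haz_coef) == K, length(times) == J)
  structure(list(n = n, J = J, K = K, miss_strength = miss_strength,
                 conf_strength = conf_strength, haz_intercept = haz_intercept,
                 haz_coef = haz_coef, haz_miss = haz_miss, times = times,
                 seed = seed),
            class = "dgp_spec")
}

rbeta_mean <- function(n, mu, conc = 10) {
  mu <- pmin(pmax(mu, 0.02), 0.98)
  stats::rbeta(n, mu * conc, (1 - mu) * conc)
}

#' Generate a longitudinal study from the structural model
#'
#' Sequential sampling in temporal order: baseline, then per time point the
#' missingness indicators, the covariates (multiplied by their observedness),
#' and the interval death indicator; death is absorbing.  Deterministic given
#' the spec's seed.
#'
#' @param spec a [dgp_spec()].
#' @return A [longitudinal_data()] object.
#' @export
generate_longitudinal <- function(spec = dgp_spec()) {
  stopifnot(inherits(spec, "dgp_spec"))
  with_seed(spec$seed, {
    n <- spec$n; J <- spec$J; K <- spec$K
    cs <- spec$conf_strength
    L0 <- cbind(L0_sev = 0.1 + 0.8 * stats::rbeta(n, 2, 2),
                L0_risk = stats::rbinom(n, 1, 0.5))
    kinds <- c(rep("continuous", max(K - 1L, 0L)), "binary")[seq_len(K)]

    covs <- array(NA_real_, dim = c(n, J, K))
    flags <- array(0, dim = c(n, J, K))  # post-death rows stay all-unobserved
    death <- matrix(NA_real_, n, J)
    alive <- rep(TRUE, n)
    Lprev <- matrix(0, n, K)   # observed-or-zero values at j - 1
    Cprev <- matrix(1, n, K)

    for (j in seq_len(J)) {
      Lcur <- matrix(NA_real_, n, K)
      Ccur <- matrix(0, n, K)
      for (k in seq_len(K)) {
        lin_c <- -0.5 - 1 * Lprev[, k] + 1 * (1 - Cprev[, k]) + 1 * L0[, 1]
        p_miss <- spec$miss_strength * stats::plogis(lin_c)
        Ccur[, k] <- stats::rbinom(n, 1, 1 - p_miss)
        mu <- stats::plogis(-0.2 + 1.2 * Lprev[, k] + cs * 0.8 * L0[, 1] +
                              (if (j == 1L) 0.3 * L0[, 2] else 0))
        val <- if (kinds[k] == "continuous") rbeta_mean(n, mu)
        else stats::rbinom(n, 1, mu)
        Lcur[, k] <- ifelse(Ccur[, k] == 1, val, NA_real_)
      }
      Lfill <- ifelse(Ccur == 1, Lcur, 0)
      lin_y <- spec$haz_intercept +
        drop(Lfill %*% (cs * spec$haz_coef)) +
        spec$haz_miss * rowSums(1 - Ccur) + cs * 0.7 * L0[, 1]
      died <- stats::rbinom(n, 1, stats::plogis(lin_y))
      death[alive, j] <- died[alive]
      covs[alive, j, ] <- Lcur[alive, ]
      flags[alive, j, ] <- Ccur[alive, ]
      alive <- alive & died == 0
      Lprev <- Lfill
      Cprev <- Ccur
    }

    meta <- data.frame(name = paste0("V", seq_len(K)), kind = kinds,
                       role = "treatment", stringsAsFactors = FALSE)
    longitudinal_data(baseline = L0, covariates = covs, miss_flags = flags,
                      death = death, times = spec$times, var_meta = meta)
  })
}

# ---- worked examples ---------------------------------------------------

#' Generate a worked comparability example
#'
#' The two-variable scenario used to compare the continuous and binary
#' parameters: A1 ~ Beta(2,2) scaled to \[0.1, 0.9\], A2 | A1 ~
#' Bernoulli(A1), no missingness, and outcome Y = A1 + A2 (continuous,
#' `"worked_linear"`) or Y ~ Bernoulli(plogis(A1 + A2))
#' (`"worked_logistic"`).  Returned as a cross-section with the requested
#' variable in the exposure role and the other as the adjustment covariate.
#'
#' @param n sample size.
#' @param scenario `"worked_linear"` or `"worked_logistic"`.
#' @param seed integer seed.
#' @param exposure `"continuous"` (A = A1, W = A2) or `"binary"`
#'   (A = A2, W = A1).
#' @return A [cross_section()].
#' @export
generate_worked_example <- function(n, scenario = c("worked_logistic",
                                                    "worked_linear"),
                                    seed = NULL,
                                    exposure = c("continuous", "binary")) {
  scenario <- match.arg(scenario)
  exposure <- match.arg(exposure)
  with_seed(seed, {
    A1 <- 0.1 + 0.8 * stats::rbeta(n, 2, 2)
    A2 <- stats::rbinom(n, 1, A1)
    Y <- if (scenario == "worked_linear") A1 + A2
    else stats::rbinom(n, 1, stats::plogis(A1 + A2))
    if (exposure == "continuous") {
      cross_section(W = matrix(A2, dimnames = list(NULL, "A2")),
                    C = rep(1, n), A = A1, Y = Y,
                    exposure_kind = "continuous",
                    meta = list(variable = "A1", scenario = scenario))
    } else {
      cross_section(W = matrix(A1, dimnames = list(NULL, "A1")),
                    C = rep(1, n), A = A2, Y = Y,
                    exposure_kind = "binary",
                    meta = list(variable = "A2", scenario = scenario))
    }
  })
}

#' True nuisances of the worked examples
#'
#' The exact outcome regression, exposure mechanism and (unit) missingness
#' mechanism of a worked-example scenario, for use in oracle evaluations of
#' the plug-in and influence-function code.
#'
#' @param scenario `"worked_linear"` or `"worked_logistic"`.
#' @param exposure `"continuous"` or `"binary"` (which variable plays A).
#' @return A [nuisance_set()].
#' @export
worked_example_nuisances <- function(scenario = c("worked_logistic",
                                                  "worked_linear"),
                                     exposure = c("continuous", "binary")) {
  scenario <- match.arg(scenario)
  exposure <- match.arg(exposure)
  mfun <- if (scenario == "worked_linear") function(x) x else stats::plogis
  dens_a1 <- function(a) stats::dbeta((a - 0.1) / 0.8, 2, 2) / 0.8
  if (exposure == "continuous") {
    # W = A2; conditional density of A1 given A2 by Bayes' rule
    # (P(A2 = 1) = E[A1] = 1/2 by symmetry of Beta(2,2))
    nuisance_set(
      qbar = function(a, W) mfun(a + as.matrix(W)[, 1]),
      g = function(a, W) {
        w <- as.matrix(W)[, 1]
        f <- dens_a1(a)
        a <- rep_len(a, length(w))
        ifelse(w == 1, a * f / 0.5, (1 - a) * f / 0.5)
      },
      kind = "continuous")
  } else {
    nuisance_set(
      qbar = function(a, W) mfun(a + as.matrix(W)[, 1]),
      g = function(W) as.matrix(W)[, 1],
      kind = "binary")
  }
}

# ---- confounded cross-sectional scenario (double-robustness grid) ------

conf_z <- function(w) 4 * (w - 0.5)^2

conf_truth <- list(
  phi = function(w1) stats::plogis(1.6 - 2.2 * conf_z(w1)),
  g = function(w2) stats::plogis(-1.0 + 2.0 * conf_z(w2)),
  qbar = function(a, c, w1, w2)
    stats::plogis(-1.0 + 0.9 * a - 0.8 * (1 - c) +
                    1.4 * conf_z(w1) + 1.1 * conf_z(w2)))

#' Generate the confounded cross-sectional scenario
#'
#' A binary-exposure scenario with informative missingness whose true
#' mechanisms are logistic in *quadratic* transforms of two independent
#' uniform covariates — so a main-terms logistic fit is inconsistent for
#' every mechanism, while a fit on the transformed design is exactly
#' correct.  The missingness mechanism depends only on W1 and the exposure
#' mechanism only on W2.  Used for the double-robustness experiments
#' together with [confounded_nuisances()] and [true_psi()].
#'
#' @param n sample size.
#' @param seed integer seed.
#' @return A [cross_section()] with binary exposure.
#' @export
generate_confounded <- function(n, seed = NULL) {
  with_seed(seed, {
    W1 <- stats::runif(n)
    W2 <- stats::runif(n)
    C <- stats::rbinom(n, 1, conf_truth$phi(W1))
    A_lat <- stats::rbinom(n, 1, conf_truth$g(W2))
    A <- ifelse(C == 1, A_lat, NA_real_)
    Y <- stats::rbinom(n, 1, conf_truth$qbar(ifelse(C == 1, A_lat, 0), C, W1, W2))
    cross_section(W = cbind(W1 = W1, W2 = W2), C = C, A = A, Y = Y,
                  exposure_kind = "binary",
                  meta = list(variable = "A", scenario = "confounded"))
  })
}

#' Fit right or wrong parametric nuisances on the confounded scenario
#'
#' "Right" fits are logistic regressions on the quadratic transforms the
#' truth uses (hence correctly specified); "wrong" fits are main-terms
#' logistic regressions in the raw covariates, which cannot capture the
#' symmetric quadratic mechanisms.
#'
#' @param cs a cross-section from [generate_confounded()].
#' @param qbar_right,g_right,phi_right logical switches.
#' @return A [nuisance_set()].
#' @export
confounded_nuisances <- function(cs, qbar_right = TRUE, g_right = TRUE,
                                 phi_right = TRUE) {
  obs <- cs$C == 1
  W1 <- cs$W[, "W1"]; W2 <- cs$W[, "W2"]
  dfull <- data.frame(W1 = W1, W2 = W2, z1 = conf_z(W1), z2 = conf_z(W2))

  qform <- if (qbar_right) y ~ A + z1 + z2 else y ~ A + W1 + W2
  dq <- cbind(dfull[obs, ], A = cs$A[obs], y = cs$Y[obs])
  qfit <- stats::glm(qform, data = dq, family = stats::binomial())
  qbar <- function(a, W) {
    W <- as.matrix(W)
    nd <- data.frame(W1 = W[, "W1"], W2 = W[, "W2"],
                     z1 = conf_z(W[, "W1"]), z2 = conf_z(W[, "W2"]),
                     A = rep_len(a, nrow(W)))
    as.numeric(stats::predict(qfit, newdata = nd, type = "response"))
  }

  gform <- if (g_right) a ~ z2 else a ~ W1 + W2
  dg <- cbind(dfull[obs, ], a = cs$A[obs])
  gfit <- stats::glm(gform, data = dg, family = stats::binomial())
  g <- function(W) {
    W <- as.matrix(W)
    nd <- data.frame(W1 = W[, "W1"], W2 = W[, "W2"],
                     z1 = conf_z(W[, "W1"]), z2 = conf_z(W[, "W2"]))
    as.numeric(stats::predict(gfit, newdata = nd, type = "response"))
  }

  pform <- if (phi_right) cc ~ z1 else cc ~ W1 + W2
  dp <- cbind(dfull, cc = cs$C)
  pfit <- stats::glm(pform, data = dp, family = stats::binomial())
  phi <- function(W) {
    W <- as.matrix(W)
    nd <- data.frame(W1 = W[, "W1"], W2 = W[, "W2"],
                     z1 = conf_z(W[, "W1"]), z2 = conf_z(W[, "W2"]))
    as.numeric(stats::predict(pfit, newdata = nd, type = "response"))
  }

  nuisance_set(qbar = qbar, g = g, phi = phi, kind = "binary",
               fits = list(qbar = qfit, g = gfit, phi = pfit))
}

# ---- oracles -----------------------------------------------------------

#' True shift-VIM parameter value of a synthetic scenario
#'
#' Computes the true parameter directly from the data-generating
#' distribution, independently of all estimation code: by adaptive
#' quadrature over the generating distribution (default) or by Monte Carlo.
#'
#' @param scenario `"worked_linear"`, `"worked_logistic"` or
#'   `"confounded"`.
#' @param target `"psi_c"` (continuous shift of A1) or `"psi_b"`
#'   (probability shift of A2 / the binary exposure).
#' @param delta shift size.
#' @param method `"quadrature"` (deterministic) or `"mc"`.
#' @param n_mc Monte Carlo draws (default 1e6).
#' @param seed seed for the Monte Carlo method.
#' @return The true parameter value.
#' @examples
#' true_psi("worked_linear", "psi_c", delta = 0.05)   # = 0.05
#' round(true_psi("worked_logistic", "psi_c", 0.01), 4)
#' @export
true_psi <- function(scenario = c("worked_logistic", "worked_linear",
                                  "confounded"),
                     target = c("psi_c", "psi_b"), delta,
                     method = c("quadrature", "mc"), n_mc = 1e6,
                     seed = NULL) {
  scenario <- match.arg(scenario)
  target <- match.arg(target)
  method <- match.arg(method)
  stopifnot(delta > 0)

  if (scenario %in% c("worked_linear", "worked_logistic")) {
    m <- if (scenario == "worked_linear") function(x) x else stats::plogis
    if (method == "quadrature") {
      f <- function(a) stats::dbeta((a - 0.1) / 0.8, 2, 2) / 0.8
      if (target == "psi_c") {
        integrand <- function(a) f(a) *
          ((1 - a) * (m(a + delta) - m(a)) + a * (m(a + delta + 1) - m(a + 1)))
      } else {
        if (delta >= 0.1)
          stop("binary positivity bound: need delta < min g(0|1,w) = 0.1")
        integrand <- function(a) f(a) * delta * (m(a + 1) - m(a))
      }
      stats::integrate(integrand, 0.1, 0.9, rel.tol = 1e-10)$value
    } else {
      with_seed(seed, {
        A1 <- 0.1 + 0.8 * stats::rbeta(n_mc, 2, 2)
        A2 <- stats::rbinom(n_mc, 1, A1)
        if (target == "psi_c") mean(m(A1 + delta + A2) - m(A1 + A2))
        else delta * mean(m(1 + A1) - m(A1))
      })
    }
  } else {
    if (target != "psi_b")
      stop("the confounded scenario has a binary exposure (psi_b only)")
    ey_i <- function(w1, w2) {
      # mean outcome under the probability-shifted exposure mechanism
      g1 <- conf_truth$g(w2)
      (g1 + delta) * conf_truth$qbar(1, 1, w1, w2) +
        (1 - g1 - delta) * conf_truth$qbar(0, 1, w1, w2)
    }
    ey_obs <- function(w1, w2) {
      # observed-world mean outcome, mixing over missingness
      g1 <- conf_truth$g(w2)
      phi <- conf_truth$phi(w1)
      phi * (g1 * conf_truth$qbar(1, 1, w1, w2) +
               (1 - g1) * conf_truth$qbar(0, 1, w1, w2)) +
        (1 - phi) * conf_truth$qbar(0, 0, w1, w2)
    }
    if (method == "quadrature") {
      G <- 201L
      u <- (seq_len(G) - 0.5) / G
      grid <- expand.grid(w1 = u, w2 = u)
      mean(ey_i(grid$w1, grid$w2) - ey_obs(grid$w1, grid$w2))
    } else {
      with_seed(seed, {
        w1 <- stats::runif(n_mc); w2 <- stats::runif(n_mc)
        mean(ey_i(w1, w2) - ey_obs(w1, w2))
      })
    }
  }
}
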