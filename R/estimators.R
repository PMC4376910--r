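# The four estimators of the shift VIM and influence-curve Wald inference.

#' VIM estimate container
#'
#' @param psi point estimate.
#' @param se influence-curve standard error.
#' @param p_value two-sided Wald p-value for psi = 0.
#' @param ci 95 percent confidence interval (length 2).
#' @param estimator one of `"tmle"`, `"ee"`, `"gcomp_ipmw"`, `"unadjusted"`.
#' @param delta shift size.
#' @param kind exposure kind.
#' @param meta provenance list (variable, times).
#' @param diagnostics list (targeting iterations, flags).
#' @return Object of class `"vim_estimate"`.
#' @export
vim_estimate <- function(psi, se, p_value, ci, estimator, delta, kind,
                         meta = list(), diagnostics = list()) {
  stopifnot(se >= 0 || is.na(se), is.na(p_value) ||
              (p_value >= 0 && p_value <= 1))
  structure(list(psi = psi, se = se, p_value = p_value, ci = ci,
                 estimator = estimator, delta = delta, kind = kind,
                 meta = meta, diagnostics = diagnostics),
            class = "vim_estimate")
}

#' @export
print.vim_estimate <- function(x, ...) {
  cat(sprintf("%s estimate of the %s-shift VIM (delta = %g)\n",
              toupper(x$estimator), x$kind, x$delta))
  cat(sprintf("  psi = %.4f  (se %.4f, 95%% CI [%.4f, %.4f], p = %s)\n",
              x$psi, x$se, x$ci[1], x$ci[2], format_pval(x$p_value)))
  if (isTRUE(x$diagnostics$out_of_range))
    cat("  note: estimate outside the parameter space [-1, 1]\n")
  if (isFALSE(x$diagnostics$converged))
    cat("  note: targeting did not converge in max_iter iterations\n")
  invisible(x)
}

format_pval <- function(p, floor = 0.001) {
  if (is.na(p)) return("NA")
  if (p < floor) sprintf("< %.3f", floor) else sprintf("%.3f", p)
}

#' Influence-curve Wald inference
#'
#' \code{se = sd(D)/sqrt(n)}, normal confidence interval, and the two-sided
#' normal p-value for psi = 0.
#'
#' @param psi point estimate.
#' @param eif an [eif_values()] object or numeric vector of influence values.
#' @param alpha confidence level complement (default 0.05).
#' @return List with `se`, `ci`, `p_value`.
#' @export
wald_inference <- function(psi, eif, alpha = 0.05) {
  D <- if (inherits(eif, "eif_values")) eif$D else as.numeric(eif)
  n <- length(D)
  stopifnot(n >= 2)
  se <- stats::sd(D) / sqrt(n)
  if (se == 0) {
    warning("degenerate inference: influence function has zero variance")
    return(list(se = 0, ci = c(psi, psi), p_value = NA_real_))
  }
  z <- stats::qnorm(1 - alpha / 2)
  list(se = se, ci = c(psi - z * se, psi + z * se),
       p_value = 2 * stats::pnorm(-abs(psi) / se))
}

# ---- estimating-equation estimator ------------------------------------

#' Estimating-equation (EE) estimator of the shift VIM
#'
#' Solves the efficient-influence-function estimating equation in closed
#' form: psi_EE is the sample mean of the EIF evaluated at psi = 0.  The
#' standard error comes from the EIF at psi_EE.  An estimate outside the
#' parameter space \[-1, 1\] is returned with an `out_of_range` flag.
#'
#' @param cs a [cross_section()].
#' @param nuis a [nuisance_set()].
#' @param delta shift size.
#' @param alpha level for the Wald interval.
#' @param control see [shiftvim_control()].
#' @return A [vim_estimate()].
#' @export
vim_ee <- function(cs, nuis, delta, alpha = 0.05,
                   control = shiftvim_control()) {
  st <- if (cs$exposure_kind == "continuous")
    cont_state(cs, nuis, delta, control) else bin_state(cs, nuis, delta, control)
  psi <- mean(state_eif(st, 0, cs$exposure_kind))
  D <- state_eif(st, psi, cs$exposure_kind)
  inf <- wald_inference(psi, D, alpha)
  vim_estimate(psi, inf$se, inf$p_value, inf$ci, "ee", delta,
               cs$exposure_kind, meta = cs$meta,
               diagnostics = list(out_of_range = abs(psi) > 1))
}

# ---- TMLE --------------------------------------------------------------

fit_epsilon <- function(y, h, offset) {
  keep <- is.finite(h) & is.finite(offset)
  if (!any(keep) || all(h[keep] == 0)) return(0)
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ -1 + h, offset = offset,
                                family = stats::binomial(), subset = keep,
                                control = list(maxit = 100L))),
    error = function(e) NULL)
  if (is.null(fit)) stop("targeting error: epsilon fit failed")
  eps <- unname(stats::coef(fit)[1L])
  if (!is.finite(eps)) 0 else eps
}

tmle_cont <- function(st, control) {
  n <- st$n
  logn <- log(n)
  obs <- st$C == 1
  eps_path <- eta_path <- numeric(0)
  converged <- FALSE

  # node-level density lookups used by the fluctuation of Qbar at the
  # shifted evaluation points (same H function as at the observed A)
  nb1 <- bin_index(st$nodes, st$edges)
  shifted <- st$nodes + st$delta
  in2 <- shifted <= st$edges[st$B + 1L] & shifted <= 1
  nb2 <- rep(NA_integer_, length(shifted))
  nb2[in2] <- bin_index(shifted[in2], st$edges)

  for (it in seq_len(control$max_iter)) {
    m <- state_m(st)
    psi <- mean(m) - mean(st$Y)
    D <- state_eif(st, psi, "continuous")
    se <- stats::sd(D) / sqrt(n)
    if (abs(mean(D)) < control$tol * se / logn) { converged <- TRUE; break }

    # (1) logistic fluctuation of Qbar with clever covariate H
    H_A <- (st$C / st$phi) * state_ratio(st, st$A)
    eps <- fit_epsilon(st$Y[obs], H_A[obs], stats::qlogis(st$qA[obs]))
    eps_path <- c(eps_path, eps)
    if (eps != 0) {
      upd <- function(q, hx) clip_prob(stats::plogis(stats::qlogis(q) + eps * hx))
      st$qA <- upd(st$qA, state_ratio(st, st$A) / st$phi)
      st$qAs <- upd(st$qAs, state_ratio(st, st$A + st$delta) / st$phi)
      dens1 <- st$P[, nb1, drop = FALSE] /
        matrix(st$widths[nb1], n, length(nb1), byrow = TRUE)
      dens2 <- matrix(0, n, length(shifted))
      if (any(in2))
        dens2[, in2] <- st$P[, nb2[in2], drop = FALSE] /
          matrix(st$widths[nb2[in2]], n, sum(in2), byrow = TRUE)
      ratio_nodes <- ifelse(dens2 > 0, dens1 / pmax(dens2, st$dens_floor), 0)
      st$QS <- clip_prob(stats::plogis(stats::qlogis(st$QS) +
                                         eps * ratio_nodes / st$phi))
    }

    # (2) multiplicative tilt of the density toward the targeting direction
    # Qbar(a + delta, 1, W) - m(W), bin-aggregated and renormalised per bin
    hbar <- state_binmeans(st)
    bA <- bin_index(st$A, st$edges)
    wobs <- 1 / st$phi[obs]
    hb_obs <- hbar[cbind(seq_len(n), bA)][obs]
    wll <- function(eta) {
      Z <- rowSums(st$P[obs, , drop = FALSE] * exp(eta * hbar[obs, , drop = FALSE]))
      sum(wobs * (eta * hb_obs - log(Z)))
    }
    eta <- tryCatch(stats::optimize(wll, c(-15, 15), maximum = TRUE)$maximum,
                    error = function(e) 0)
    if (abs(eta) > 14.5) eta <- 0  # boundary solution: treat as no update
    eta_path <- c(eta_path, eta)
    if (eta != 0) {
      st$P <- st$P * exp(eta * hbar)
      st$P <- st$P / rowSums(st$P)
    }
    if (eps == 0 && eta == 0) break  # no further movement possible
  }
  m <- state_m(st)
  psi <- mean(m) - mean(st$Y)
  D <- state_eif(st, psi, "continuous")
  list(psi = psi, D = D, iterations = length(eps_path), converged = converged,
       eps_path = eps_path, eta_path = eta_path,
       ey_shift = mean(m))
}

tmle_bin <- function(st, control) {
  n <- st$n
  logn <- log(n)
  obs <- st$C == 1
  eps_path <- eta_path <- numeric(0)
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    psi <- mean(bin_m(st)) - mean(st$Y)
    D <- state_eif(st, psi, "binary")
    se <- stats::sd(D) / sqrt(n)
    if (abs(mean(D)) < control$tol * se / logn) { converged <- TRUE; break }

    gA <- ifelse(st$A == 1, st$g1, 1 - st$g1)
    gstarA <- ifelse(st$A == 1, st$g1 + st$delta, 1 - st$g1 - st$delta)
    H_A <- (st$C / st$phi) * gstarA / pmax(gA, st$dens_floor)
    qA <- ifelse(st$A == 1, st$q1, st$q0)
    eps <- fit_epsilon(st$Y[obs], H_A[obs], stats::qlogis(qA[obs]))
    eps_path <- c(eps_path, eps)
    if (eps != 0) {
      h1 <- (st$g1 + st$delta) / pmax(st$g1, st$dens_floor) / st$phi
      h0 <- (1 - st$g1 - st$delta) / pmax(1 - st$g1, st$dens_floor) / st$phi
      st$q1 <- clip_prob(stats::plogis(stats::qlogis(st$q1) + eps * h1))
      st$q0 <- clip_prob(stats::plogis(stats::qlogis(st$q0) + eps * h0))
    }

    # one-parameter logistic tilt of g along the contrast direction,
    # weighted maximum likelihood on the observed-exposure rows
    d <- st$q1 - st$q0
    eta <- 0
    for (nwt in 1:25) {
      geta <- stats::plogis(stats::qlogis(st$g1) + eta * d)
      score <- sum((1 / st$phi[obs]) * (st$A[obs] - geta[obs]) * d[obs])
      info <- sum((1 / st$phi[obs]) * geta[obs] * (1 - geta[obs]) * d[obs]^2)
      if (info < 1e-12) break
      step <- score / info
      eta <- eta + step
      if (abs(step) < 1e-10) break
    }
    eta_path <- c(eta_path, eta)
    if (eta != 0) {
      st$g1 <- stats::plogis(stats::qlogis(st$g1) + eta * d)
      # keep the shifted mechanism a valid probability
      st$g1 <- pmin(pmax(st$g1, 1e-6), 1 - st$delta - 1e-6)
    }
    if (eps == 0 && eta == 0) break
  }
  psi <- mean(bin_m(st)) - mean(st$Y)
  D <- state_eif(st, psi, "binary")
  list(psi = psi, D = D, iterations = length(eps_path), converged = converged,
       eps_path = eps_path, eta_path = eta_path,
       ey_shift = mean(bin_m(st)))
}

#' Targeted minimum loss-based estimator (TMLE) of the shift VIM
#'
#' Iterative targeting: each iteration (1) fluctuates the outcome regression
#' along a one-parameter logistic submodel with the clever covariate, with
#' epsilon fitted by maximum likelihood, and (2) fluctuates the exposure
#' mechanism by a one-parameter multiplicative tilt in the direction
#' \code{Qbar(a + delta, 1, W) - m(W)} (logistic tilt along the outcome
#' contrast in the binary case), renormalised per bin.  Iteration stops when
#' \code{|mean EIF| < se / log(n)} or `max_iter` is reached; a
#' non-convergent fit is returned with a flag.  The final estimate is the
#' plug-in at the targeted fits, so the estimated mean counterfactual
#' outcome always respects \[0, 1\].
#'
#' @inheritParams vim_ee
#' @return A [vim_estimate()] with targeting diagnostics.
#' @export
vim_tmle <- function(cs, nuis, delta, alpha = 0.05,
                     control = shiftvim_control()) {
  if (!is_binary01(cs$Y)) stop("TMLE targeting requires a binary outcome")
  st <- if (cs$exposure_kind == "continuous")
    cont_state(cs, nuis, delta, control) else bin_state(cs, nuis, delta, control)
  res <- if (cs$exposure_kind == "continuous")
    tmle_cont(st, control) else tmle_bin(st, control)
  inf <- wald_inference(res$psi, res$D, alpha)
  vim_estimate(res$psi, inf$se, inf$p_value, inf$ci, "tmle", delta,
               cs$exposure_kind, meta = cs$meta,
               diagnostics = list(iterations = res$iterations,
                                  converged = res$converged,
                                  eps_path = res$eps_path,
                                  eta_path = res$eta_path,
                                  ey_shift = res$ey_shift,
                                  mean_eif = mean(res$D)))
}

# ---- Gcomp/IPMW and unadjusted ----------------------------------------

fit_stepwise_or_main <- function(df, y) {
  fam <- if (is_binary01(y)) stats::binomial() else stats::gaussian()
  full <- suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                      family = fam, control = list(maxit = 50L)))
  out <- tryCatch(
    suppressWarnings(stats::step(full, scope = list(lower = ~1,
                                                    upper = stats::formula(full)),
                                 direction = "both", trace = 0)),
    error = function(e) {
      warning("stepwise selection failed; using main-terms fit")
      full
    })
  out
}

gcomp_core <- function(cs, delta, alpha, control, adjusted) {
  obs <- cs$C == 1
  n <- cs$n
  if (adjusted) {
    dfW <- as_learner_frame(cs$W)
    dfQ <- cbind(A = cs$A[obs], dfW[obs, , drop = FALSE])
  } else {
    dfW <- data.frame(row.names = seq_len(n))
    dfQ <- data.frame(A = cs$A[obs])
  }
  qfit <- fit_stepwise_or_main(dfQ, cs$Y[obs])
  qpred <- function(avals, rows) {
    nd <- if (adjusted) cbind(A = avals, dfW[rows, , drop = FALSE])
    else data.frame(A = avals)
    as.numeric(stats::predict(qfit, newdata = nd, type = "response"))
  }
  phi <- if (all(obs)) {
    rep(1, n)
  } else if (adjusted) {
    pfit <- fit_stepwise_or_main(dfW, cs$C)
    pmax(as.numeric(stats::predict(pfit, newdata = dfW, type = "response")),
         control$phi_floor)
  } else {
    rep(max(mean(cs$C), control$phi_floor), n)
  }

  A_fill <- ifelse(obs, cs$A, if (cs$exposure_kind == "binary") 0 else 0.5)
  rows <- seq_len(n)
  if (cs$exposure_kind == "continuous") {
    qshift <- qpred(A_fill + delta, rows)
    term <- (cs$C / phi) * qshift
  } else {
    qA <- qpred(A_fill, rows)
    q1 <- qpred(rep(1, n), rows)
    q0 <- qpred(rep(0, n), rows)
    term <- (cs$C / phi) * (qA + delta * (q1 - q0))
  }
  contrib <- term - cs$Y
  psi <- mean(contrib)
  D <- contrib - psi  # naive plug-in influence function (nuisances ignored)
  inf <- wald_inference(psi, D, alpha)
  vim_estimate(psi, inf$se, inf$p_value, inf$ci,
               if (adjusted) "gcomp_ipmw" else "unadjusted",
               delta, cs$exposure_kind, meta = cs$meta,
               diagnostics = list(out_of_range = abs(psi) > 1))
}

#' G-computation / inverse-probability-of-missingness estimator
#'
#' Fits the outcome regression and the missingness mechanism by AIC-based
#' bidirectional stepwise logistic regression (falling back to the
#' main-terms fit on failure) and evaluates
#' \code{mean_i [ (C_i / phi(W_i)) Qbar(A_i + delta, 1, W_i) - Y_i ]}
#' for a continuous exposure, or the probability-shift analogue
#' \code{mean_i [ (C_i / phi(W_i)) (Qbar(A_i,1,W_i) + delta (Qbar(1,1,W_i) -
#' Qbar(0,1,W_i))) - Y_i ]} for a binary one.  Standard errors use the naive
#' plug-in influence function, ignoring nuisance estimation.
#'
#' @inheritParams vim_ee
#' @return A [vim_estimate()].
#' @export
vim_gcomp_ipmw <- function(cs, delta, alpha = 0.05,
                           control = shiftvim_control()) {
  gcomp_core(cs, delta, alpha, control, adjusted = TRUE)
}

#' Unadjusted estimator
#'
#' Identical to [vim_gcomp_ipmw()] but with an intercept-only covariate
#' vector: no confounding adjustment and a marginal missingness probability.
#'
#' @inheritParams vim_ee
#' @return A [vim_estimate()].
#' @export
vim_unadjusted <- function(cs, delta, alpha = 0.05,
                           control = shiftvim_control()) {
  gcomp_core(cs, delta, alpha, control, adjusted = FALSE)
}
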