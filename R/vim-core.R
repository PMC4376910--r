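# Target parameters, clever covariates and efficient influence functions
# for the continuous-shift and binary probability-shift variable importance
# measures.
#
# Continuous exposure, shift delta:
#   psi_c = E_W  int Qbar(a + delta, 1, W) g(a | 1, W) da  -  E(Y)
# Binary exposure, probability shift delta:
#   psi_b = E_W [ sum_a g*(a | W) Qbar(a, 1, W) ] - E(Y),
#   with g*(1|W) = g(1|1,W) + delta (requires delta < min_w g(0|1,w)).
# The binary contrast uses Qbar(1,1,W) - Qbar(0,1,W) (the intervention on A
# with C fixed at 1).

#' Plug-in value of the continuous-shift VIM
#'
#' Computes the substitution estimator
#' \code{mean_i m(W_i) - mean_i Y_i}, where
#' \code{m(W) = int Qbar(a + delta, 1, W) g(a | 1, W) da} is evaluated by
#' midpoint quadrature (exact against the piecewise-constant density) and the
#' empirical distribution of W is the sample.
#'
#' @param nuis a [nuisance_set()] (continuous kind).
#' @param cs a [cross_section()] with continuous exposure.
#' @param delta shift size on the \[0,1\] exposure scale.
#' @param control see [shiftvim_control()].
#' @return Scalar parameter value.
#' @export
plug_in_psi_c <- function(nuis, cs, delta, control = shiftvim_control()) {
  st <- cont_state(cs, nuis, delta, control)
  val <- mean(state_m(st)) - mean(st$Y)
  if (!is.finite(val)) stop("non-finite plug-in integral (check nuisances)")
  val
}

#' Plug-in value of the binary probability-shift VIM
#'
#' \code{mean_i [ (g1 + delta) Qbar(1,1,W_i) + (1 - g1 - delta)
#' Qbar(0,1,W_i) ] - mean_i Y_i} with \code{g1 = g(1|1,W_i)}.
#'
#' @inheritParams plug_in_psi_c
#' @return Scalar parameter value.
#' @export
plug_in_psi_b <- function(nuis, cs, delta, control = shiftvim_control()) {
  st <- bin_state(cs, nuis, delta, control)
  val <- mean(bin_m(st)) - mean(st$Y)
  if (!is.finite(val)) stop("non-finite plug-in value (check nuisances)")
  val
}

# Plug-in dispatching on exposure kind (internal).
plug_in_psi <- function(nuis, cs, delta, control = shiftvim_control()) {
  if (cs$exposure_kind == "continuous") plug_in_psi_c(nuis, cs, delta, control)
  else plug_in_psi_b(nuis, cs, delta, control)
}

#' Clever covariate of the targeting step
#'
#' Returns the weight function H(a, c, w) used in the logistic fluctuation
#' of the outcome regression: for a continuous exposure
#' \code{H = (c / phi(1|w)) g(a - delta | 1, w) / g(a | 1, w)} (0 when the
#' shifted-back point leaves the support), for a binary exposure
#' \code{H = (c / phi(1|w)) g*(a | w) / g(a | 1, w)}.  The density floor is
#' applied to ratio denominators; \code{H = 0} when \code{c = 0}.
#'
#' @param nuis a [nuisance_set()].
#' @param delta shift size.
#' @param control see [shiftvim_control()].
#' @return A function \code{(a, c, W) -> numeric}.
#' @export
clever_covariate <- function(nuis, delta, control = shiftvim_control()) {
  force(nuis); force(delta); force(control)
  function(a, c, W) {
    W <- as.matrix(W)
    n <- nrow(W)
    a <- rep_len(as.numeric(a), n)
    c <- rep_len(as.numeric(c), n)
    phi <- pmax(nuis$phi(W), control$phi_floor)
    if (nuis$kind == "continuous") {
      gden <- if (inherits(nuis$g, "hist_density"))
        density_eval(nuis$g, a, W) else nuis$g(a, W)
      gnum <- if (inherits(nuis$g, "hist_density"))
        density_eval(nuis$g, a - delta, W) else {
          out <- numeric(n)
          ok <- (a - delta) >= 0 & (a - delta) <= 1
          if (any(ok)) out[ok] <- nuis$g(a[ok] - delta, W[ok, , drop = FALSE])
          out
        }
      ratio <- ifelse(gden > 0, gnum / pmax(gden, control$dens_floor), 0)
    } else {
      g1 <- clip_prob(nuis$g(W))
      gstar <- ifelse(a == 1, g1 + delta, 1 - g1 - delta)
      gobs <- ifelse(a == 1, g1, 1 - g1)
      ratio <- gstar / pmax(gobs, control$dens_floor)
    }
    (c / phi) * ratio
  }
}

# EIF contributions from an evaluated state at a candidate psi (internal).
state_eif <- function(st, psi, kind) {
  ip <- st$C / st$phi
  if (kind == "continuous") {
    ratio <- state_ratio(st, st$A)
    m <- state_m(st)
    ip * (ratio * (st$Y - st$qA) + st$qAs - m) + m - st$Y - psi
  } else {
    gA <- ifelse(st$A == 1, st$g1, 1 - st$g1)
    gstarA <- ifelse(st$A == 1, st$g1 + st$delta, 1 - st$g1 - st$delta)
    ratio <- gstarA / pmax(gA, st$dens_floor)
    qA <- ifelse(st$A == 1, st$q1, st$q0)
    mg <- st$g1 * st$q1 + (1 - st$g1) * st$q0
    mb <- bin_m(st)
    ip * (ratio * (st$Y - qA) + qA - mg) + mb - st$Y - psi
  }
}

#' Efficient influence function values
#'
#' Per-observation contributions of the efficient influence function of the
#' shift VIM at a candidate parameter value, evaluated under the supplied
#' nuisances.  Assembled so that the sample mean is exactly zero when `psi`
#' equals the estimating-equation solution.
#'
#' @param nuis a [nuisance_set()].
#' @param cs a [cross_section()].
#' @param delta shift size.
#' @param psi parameter value at which to evaluate; default: the plug-in.
#' @param control see [shiftvim_control()].
#' @return Object of class `"eif_values"`: list with `D` (length-n vector),
#'   `plug_in`, and `psi`.
#' @export
eif_values <- function(nuis, cs, delta, psi = NULL,
                       control = shiftvim_control()) {
  st <- if (cs$exposure_kind == "continuous")
    cont_state(cs, nuis, delta, control) else bin_state(cs, nuis, delta, control)
  plug_in <- if (cs$exposure_kind == "continuous")
    mean(state_m(st)) - mean(st$Y) else mean(bin_m(st)) - mean(st$Y)
  if (is.null(psi)) psi <- plug_in
  D <- state_eif(st, psi, cs$exposure_kind)
  structure(list(D = D, plug_in = plug_in, psi = psi), class = "eif_values")
}
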