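# Nuisance container and the evaluated per-observation state on which the
# parameter, influence-function and estimator code operates.

#' Bundle fitted (or known) nuisance functions
#'
#' Holds the outcome regression Qbar(a, w) = E(Y | A = a, C = 1, W = w), the
#' exposure mechanism g, and the missingness mechanism phi(w) =
#' P(C = 1 | W = w).  The empirical covariate distribution is the sample
#' itself.  All functions must be vectorised over rows of `W`.
#'
#' @param qbar function(a, W) -> numeric; `a` scalar or length `nrow(W)`.
#' @param g for a binary exposure: function(W) -> P(A = 1 | C = 1, W); for a
#'   continuous exposure: a [density_fit()] object, or a function
#'   (a, W) -> conditional density values.
#' @param phi function(W) -> P(C = 1 | W); default: no missingness (phi = 1).
#' @param kind `"continuous"` or `"binary"`.
#' @param fits optional list of underlying fitted objects, for diagnostics.
#' @return Object of class `"nuisance_set"`.
#' @export
nuisance_set <- function(qbar, g, phi = NULL,
                         kind = c("continuous", "binary"), fits = list()) {
  kind <- match.arg(kind)
  if (is.null(phi)) phi <- function(W) rep(1, nrow(as.matrix(W)))
  stopifnot(is.function(qbar), is.function(phi))
  if (kind == "binary" && !is.function(g))
    stop("binary exposure needs g as a function of W")
  if (kind == "continuous" && !(is.function(g) || inherits(g, "hist_density")))
    stop("continuous exposure needs g as a density function or hist_density fit")
  structure(list(qbar = qbar, g = g, phi = phi, kind = kind, fits = fits),
            class = "nuisance_set")
}

#' Numerical controls for estimation
#'
#' @param nodes_per_bin midpoint-quadrature nodes per histogram cell used to
#'   integrate the outcome regression against the conditional density
#'   (default 10).
#' @param grid_cells number of equal cells used to discretise a
#'   user-supplied (functional) continuous density (default 100).
#' @param dens_floor floor applied to density values in ratio denominators
#'   (default 1e-3), taming practical positivity violations.
#' @param phi_floor floor for the missingness mechanism in inverse weights
#'   (default 0.01).
#' @param max_iter maximum targeting iterations (default 20).
#' @param tol convergence scale: targeting stops when
#'   |mean EIF| < se / log(n) * tol (default 1).
#' @return List of control settings.
#' @export
shiftvim_control <- function(nodes_per_bin = 10L, grid_cells = 100L,
                             dens_floor = 1e-3, phi_floor = 0.01,
                             max_iter = 20L, tol = 1) {
  list(nodes_per_bin = nodes_per_bin, grid_cells = grid_cells,
       dens_floor = dens_floor, phi_floor = phi_floor,
       max_iter = max_iter, tol = tol)
}

#' Fit all nuisances for a cross-section with the super learner
#'
#' Fits the outcome regression Qbar on the observed-exposure rows, the
#' missingness mechanism phi on all rows (unless the exposure is fully
#' observed, in which case phi = 1), and the exposure mechanism g: a
#' super-learner classification fit for a binary exposure, a stacked
#' histogram density ([density_fit()]) for a continuous one.
#'
#' @param cs a [cross_section()].
#' @param sl_library candidate names for the binary-outcome fits.
#' @param V folds.
#' @param seed optional integer seed (sub-seeds are derived per nuisance).
#' @param density_candidates candidate grid for [density_fit()].
#' @return A [nuisance_set()].
#' @export
fit_nuisances <- function(cs, sl_library = sl_library_default(), V = 10L,
                          seed = NULL,
                          density_candidates = expand.grid(
                            n_bins = c(2L, 5L, 10L, 20L),
                            placement = c("equal_width", "equal_frequency"),
                            stringsAsFactors = FALSE)) {
  stopifnot(inherits(cs, "cross_section"))
  obs <- cs$C == 1
  W <- cs$W

  # outcome regression E(Y | A, C = 1, W)
  XQ <- cbind(A = cs$A[obs], W[obs, , drop = FALSE])
  qfit <- sl_fit(XQ, cs$Y[obs], library = sl_library, V = V,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  qbar <- function(a, W) {
    W <- as.matrix(W)
    predict(qfit, cbind(A = rep_len(a, nrow(W)), W))
  }

  # missingness mechanism P(C = 1 | W)
  if (all(obs)) {
    phi <- function(W) rep(1, nrow(as.matrix(W)))
    pfit <- NULL
  } else {
    pfit <- sl_fit(W, cs$C, library = sl_library, V = V,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
    phi <- function(W) predict(pfit, W)
  }

  # exposure mechanism
  if (cs$exposure_kind == "binary") {
    gfit <- sl_fit(W[obs, , drop = FALSE], cs$A[obs], library = sl_library,
                   V = V, seed = if (is.null(seed)) NULL else derive_seed(seed, 3L))
    g <- function(W) predict(gfit, W)
  } else {
    gfit <- density_fit(cs$A[obs], W[obs, , drop = FALSE],
                        candidates = density_candidates, V = V,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, 3L))
    g <- gfit
  }

  nuisance_set(qbar = qbar, g = g, phi = phi, kind = cs$exposure_kind,
               fits = list(qbar = qfit, phi = pfit, g = gfit))
}

# ---- evaluated state ---------------------------------------------------

# Batched evaluation of qbar at every (node, observation) pair, chunked over
# nodes so temporaries stay bounded (~5e6 evaluation rows per chunk).
eval_qbar_grid <- function(qbar, W, avec) {
  n <- nrow(W)
  S <- length(avec)
  out <- matrix(NA_real_, n, S)
  step <- max(1L, floor(5e6 / n))
  for (s0 in seq(1L, S, by = step)) {
    cols <- s0:min(s0 + step - 1L, S)
    Wrep <- W[rep(seq_len(n), times = length(cols)), , drop = FALSE]
    arep <- rep(avec[cols], each = n)
    out[, cols] <- matrix(qbar(arep, Wrep), n, length(cols))
  }
  out
}

# Continuous-exposure state: union-cell bin probabilities P (n x B),
# quadrature nodes, and all outcome-regression evaluations needed by the
# plug-in, the influence function and the targeting steps.
cont_state <- function(cs, nuis, delta, control = shiftvim_control()) {
  stopifnot(cs$exposure_kind == "continuous", nuis$kind == "continuous")
  n <- cs$n
  W <- cs$W

  if (inherits(nuis$g, "hist_density")) {
    edges <- density_union_edges(nuis$g)
    P <- density_union_probs(nuis$g, W, edges)
  } else {
    B0 <- control$grid_cells
    edges <- seq(0, 1, length.out = B0 + 1L)
    mids <- (edges[-1L] + edges[-(B0 + 1L)]) / 2
    P <- vapply(mids, function(m) nuis$g(m, W), numeric(n)) * (1 / B0)
    rs <- rowSums(P)
    if (any(rs <= 0)) stop("user density evaluates to zero everywhere for some rows")
    P <- P / rs
  }
  B <- length(edges) - 1L
  widths <- diff(edges)

  # refine to node-cell resolution: each cell is subdivided into
  # `nodes_per_bin` equal sub-cells carrying equal shares of the cell's
  # probability (exact for a piecewise-constant density).  The quadrature
  # node of a sub-cell is its midpoint, so the targeting tilt's sufficient
  # statistic coincides with the pointwise Qbar(a + delta, W) evaluations
  # that enter the influence function.
  npb <- control$nodes_per_bin
  if (npb > 1L) {
    fine <- unlist(lapply(seq_len(B), function(b)
      edges[b] + widths[b] * seq_len(npb - 1L) / npb))
    P <- P[, rep(seq_len(B), each = npb), drop = FALSE] / npb
    edges <- sort(c(edges, fine))
    B <- length(edges) - 1L
    widths <- diff(edges)
  }
  nodes <- (edges[-1L] + edges[-(B + 1L)]) / 2
  node_bin <- seq_len(B)
  npb <- 1L

  A_fill <- ifelse(cs$C == 1, cs$A, 0.5)  # placeholder; masked by C
  clip_y <- is_binary01(cs$Y)  # only bound regressions for a binary outcome
  cl <- if (clip_y) clip_prob else identity
  st <- list(
    n = n, W = W, C = cs$C, A = A_fill, Y = cs$Y, delta = delta,
    edges = edges, widths = widths, B = B, P = P,
    nodes = nodes, node_bin = node_bin, npb = npb,
    phi = pmax(nuis$phi(W), control$phi_floor),
    QS = cl(eval_qbar_grid(nuis$qbar, W, nodes + delta)),
    qA = cl(nuis$qbar(A_fill, W)),
    qAs = cl(nuis$qbar(A_fill + delta, W)),
    dens_floor = control$dens_floor)
  st
}

# Per-observation density lookups from the union-cell representation.
state_dens <- function(st, x) {
  x <- rep_len(x, st$n)
  out <- numeric(st$n)
  inside <- x >= st$edges[1L] & x <= st$edges[st$B + 1L] & x >= 0 & x <= 1
  if (any(inside)) {
    b <- bin_index(x[inside], st$edges)
    out[inside] <- st$P[cbind(which(inside), b)] / st$widths[b]
  }
  out
}

# Density ratio g(x - delta) / g(x) with the support convention: 0 whenever
# the numerator point falls outside the support, 0 where the denominator
# density is exactly 0 (the point cannot be observed), floored denominator
# otherwise.
state_ratio <- function(st, x) {
  num <- state_dens(st, x - st$delta)
  den <- state_dens(st, x)
  out <- numeric(st$n)
  pos <- den > 0
  out[pos] <- num[pos] / pmax(den[pos], st$dens_floor)
  out
}

# Bin means of the node-level outcome-regression evaluations; m(W) is then
# the exact integral of the piecewise-constant density against the midpoint
# rule: m_i = sum_b P[i, b] * mean_{nodes in b} Qbar(node + delta, W_i).
state_binmeans <- function(st) {
  if (st$npb == 1L) return(st$QS)  # one node per cell after refinement
  out <- matrix(0, st$n, st$B)
  for (b in seq_len(st$B)) {
    cols <- which(st$node_bin == b)
    out[, b] <- rowMeans(st$QS[, cols, drop = FALSE])
  }
  out
}

state_m <- function(st) rowSums(st$P * state_binmeans(st))

# Binary-exposure state.
bin_state <- function(cs, nuis, delta, control = shiftvim_control()) {
  stopifnot(cs$exposure_kind == "binary", nuis$kind == "binary")
  n <- cs$n
  W <- cs$W
  g1 <- clip_prob(nuis$g(W))
  if (delta >= min(1 - g1))
    stop(sprintf(
      "delta = %g violates the binary positivity bound: min estimated g(0|1,w) = %g",
      delta, min(1 - g1)))
  A_fill <- ifelse(cs$C == 1, cs$A, 0)
  cl <- if (is_binary01(cs$Y)) clip_prob else identity
  list(n = n, W = W, C = cs$C, A = A_fill, Y = cs$Y, delta = delta,
       phi = pmax(nuis$phi(W), control$phi_floor),
       g1 = g1,
       q1 = cl(nuis$qbar(1, W)),
       q0 = cl(nuis$qbar(0, W)),
       dens_floor = control$dens_floor)
}

bin_m <- function(st) {
  # mean outcome under the probability-shifted mechanism g*(1|w) = g1 + delta
  (st$g1 + st$delta) * st$q1 + (1 - st$g1 - st$delta) * st$q0
}

# ---- positivity diagnostics -------------------------------------------

#' Positivity diagnostics for a cross-section
#'
#' Reports quantiles of the estimated missingness mechanism and of the
#' exposure mechanism evaluated at the observed and intervened exposure
#' values, and flags observations whose denominators fall below the
#' configured floors.
#'
#' @param nuis a [nuisance_set()].
#' @param cs a [cross_section()].
#' @param delta shift size.
#' @param control see [shiftvim_control()].
#' @return Object of class `"positivity_report"` (list of quantile tables
#'   and flag counts).
#' @export
positivity_check <- function(nuis, cs, delta, control = shiftvim_control()) {
  qs <- c(0, 0.01, 0.05, 0.25, 0.5)
  phi <- nuis$phi(cs$W)
  out <- list(delta = delta,
              phi_quantiles = stats::quantile(phi, qs),
              n_phi_flagged = sum(phi < control$phi_floor))
  obs <- cs$C == 1
  if (cs$exposure_kind == "continuous") {
    st <- cont_state(cs, nuis, delta, control)
    gA <- state_dens(st, st$A)[obs]
    gAm <- state_dens(st, st$A - delta)[obs]
    out$g_at_A_quantiles <- stats::quantile(gA, qs)
    out$g_at_A_minus_delta_quantiles <- stats::quantile(gAm, qs)
    out$n_g_flagged <- sum(gA < control$dens_floor)
  } else {
    g1 <- nuis$g(cs$W)
    out$g1_quantiles <- stats::quantile(g1, qs)
    out$min_g0 <- min(1 - g1)
    out$delta_bound_ok <- delta < min(1 - g1)
    out$n_g_flagged <- sum(pmin(g1, 1 - g1) < control$dens_floor)
  }
  structure(out, class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Positivity diagnostics (delta =", x$delta, ")\n")
  cat("  phi(1|W) quantiles:\n")
  print(round(x$phi_quantiles, 4))
  if (!is.null(x$g_at_A_quantiles)) {
    cat("  g(A|1,W) quantiles:\n"); print(round(x$g_at_A_quantiles, 4))
    cat("  g(A-delta|1,W) quantiles:\n")
    print(round(x$g_at_A_minus_delta_quantiles, 4))
  } else {
    cat("  g(1|W) quantiles:\n"); print(round(x$g1_quantiles, 4))
    cat(sprintf("  min g(0|1,w) = %.4f; delta bound satisfied: %s\n",
                x$min_g0, x$delta_bound_ok))
  }
  cat(sprintf("  flagged: %d (phi), %d (g)\n", x$n_phi_flagged, x$n_g_flagged))
  invisible(x)
}
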