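# Piecewise-constant conditional density estimation for a continuous
# exposure on [0,1]: each candidate is a histogram whose bin-membership
# probabilities are fitted by a hazard-style sequential binary regression on
# the covariates; candidates (number of bins x bin placement) are combined
# by cross-validated stacking on the log-density.

hist_edges <- function(A, n_bins, placement) {
  if (placement == "equal_width") {
    edges <- seq(0, 1, length.out = n_bins + 1L)
  } else {
    probs <- seq(0, 1, length.out = n_bins + 1L)
    edges <- unique(c(0, stats::quantile(A, probs = probs[-c(1, n_bins + 1L)],
                                         names = FALSE, type = 7), 1))
  }
  if (length(edges) < 3L && n_bins > 1L) return(NULL)  # collapsed bins
  edges
}

bin_index <- function(a, edges) {
  b <- findInterval(a, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

# Fit one histogram candidate: sequential ("hazard") logistic regressions
# P(A in bin b | A not in earlier bins, W).
fit_hist_candidate <- function(A, df, edges, hmin = 1e-3) {
  B <- length(edges) - 1L
  bins <- bin_index(A, edges)
  hazard_fits <- vector("list", B - 1L)
  if (B > 1L) {
    for (b in seq_len(B - 1L)) {
      atrisk <- bins >= b
      yb <- as.numeric(bins[atrisk] == b)
      sub <- df[atrisk, , drop = FALSE]
      hazard_fits[[b]] <- if (sum(atrisk) < 10L || length(unique(yb)) < 2L) {
        # empty at-risk set: the remaining mass is negligible; split it
        # evenly so downstream evaluations stay finite
        p_const <- if (!any(atrisk)) 0.5 else clip_prob(mean(yb), hmin)
        list(type = "const", p = p_const)
      } else {
        fit <- tryCatch(
          suppressWarnings(stats::glm(yb ~ ., data = cbind(sub, yb = yb),
                                      family = stats::binomial(),
                                      control = list(maxit = 50L))),
          error = function(e) NULL)
        if (is.null(fit)) list(type = "const", p = clip_prob(mean(yb), hmin))
        else list(type = "glm", fit = fit)
      }
    }
  }
  list(edges = edges, hazard_fits = hazard_fits, hmin = hmin)
}

# Bin-membership probability matrix P(bin | w), rows = observations of df.
hist_bin_probs <- function(cand, df) {
  B <- length(cand$edges) - 1L
  n <- nrow(df)
  P <- matrix(0, n, B)
  surv <- rep(1, n)
  if (B > 1L) {
    for (b in seq_len(B - 1L)) {
      hf <- cand$hazard_fits[[b]]
      h <- if (hf$type == "const") rep(hf$p, n) else
        as.numeric(suppressWarnings(
          stats::predict(hf$fit, newdata = df, type = "response")))
      h <- pmin(pmax(h, cand$hmin), 1 - cand$hmin)
      P[, b] <- surv * h
      surv <- surv * (1 - h)
    }
  }
  P[, B] <- surv
  P
}

#' Fit a stacked piecewise-constant conditional density
#'
#' Estimates the conditional density g(a | W) of a continuous exposure on
#' \[0,1\] by cross-validated stacking of histogram candidates.  Each
#' candidate is indexed by its number of bins and bin placement
#' (equal-width or equal-frequency); bin membership given covariates is
#' fitted by sequential binary (hazard) logistic regressions.  Stacking
#' weights maximise the cross-validated log-density of the mixture.
#'
#' @param A observed exposure values in (0,1) (rows with the exposure
#'   observed only).
#' @param W covariate matrix aligned with `A`.
#' @param candidates data.frame with columns `n_bins` and `placement`;
#'   default grid: bins in \{2, 5, 10, 20\} crossed with both placements.
#' @param V folds for the stacking cross-validation (default 10).
#' @param seed optional integer for reproducible folds.
#' @return Object of class `"hist_density"`: candidate fits, `weights`,
#'   per-candidate cross-validated log-likelihoods (`cv_loglik`).
#' @examples
#' set.seed(2)
#' A <- runif(400)
#' W <- matrix(rbinom(400, 1, 0.5))
#' g <- density_fit(A, W, candidates = data.frame(n_bins = 5,
#'                  placement = "equal_width"), V = 5, seed = 2)
#' density_eval(g, 0.3, W[1, , drop = FALSE])
#' @export
density_fit <- function(A, W,
                        candidates = expand.grid(
                          n_bins = c(2L, 5L, 10L, 20L),
                          placement = c("equal_width", "equal_frequency"),
                          stringsAsFactors = FALSE),
                        V = 10L, seed = NULL) {
  A <- as.numeric(A)
  stopifnot(all(A > 0 & A < 1), !any(is.na(A)))
  df <- as_learner_frame(W)
  stopifnot(nrow(df) == length(A))
  n <- length(A)

  specs <- list()
  n_dropped <- 0L
  for (r in seq_len(nrow(candidates))) {
    nb <- candidates$n_bins[r]
    edges <- if (nb > n) NULL  # fewer observations than bins: drop
    else hist_edges(A, nb, as.character(candidates$placement[r]))
    if (is.null(edges)) { n_dropped <- n_dropped + 1L; next }
    specs[[length(specs) + 1L]] <- list(n_bins = nb,
                                        placement = as.character(candidates$placement[r]),
                                        edges = edges)
  }
  if (n_dropped > 0L)
    warning(n_dropped, " density candidate(s) dropped (too few observations ",
            "or collapsed bin edges)")
  if (!length(specs)) stop("all density candidates dropped (too few observations)")
  k <- length(specs)

  if (k == 1L) {
    weights <- 1
    cvll <- NA_real_
  } else {
    folds <- with_seed(seed, make_folds(rep(0, n), V, stratify = FALSE))
    Dmat <- matrix(NA_real_, n, k)
    for (ci in seq_len(k)) {
      for (v in seq_len(V)) {
        test <- folds == v
        cand <- fit_hist_candidate(A[!test], df[!test, , drop = FALSE],
                                   specs[[ci]]$edges)
        P <- hist_bin_probs(cand, df[test, , drop = FALSE])
        widths <- diff(cand$edges)
        b <- bin_index(A[test], cand$edges)
        Dmat[test, ci] <- P[cbind(seq_len(sum(test)), b)] / widths[b]
      }
    }
    Dmat <- pmax(Dmat, 1e-10)
    weights <- optimize_simplex_weights(
      function(w) -mean(log(pmax(drop(Dmat %*% w), 1e-12))), k)
    cvll <- c(colMeans(log(Dmat)), ensemble = mean(log(pmax(drop(Dmat %*% weights), 1e-12))))
  }

  fits <- lapply(specs, function(s) fit_hist_candidate(A, df, s$edges))
  structure(list(candidates = fits, specs = specs,
                 weights = as.numeric(weights), cv_loglik = cvll,
                 train_cols = names(df)),
            class = "hist_density")
}

#' Evaluate a fitted conditional density
#'
#' Returns 0 outside \[0,1\]; inside, the weighted mixture of the candidate
#' piecewise-constant densities P(bin(a) | w) / width(bin(a)).
#'
#' @param g a [density_fit()] object.
#' @param a evaluation point(s): scalar or vector of length `nrow(W)`.
#' @param W covariate matrix (rows at which to evaluate).
#' @return Nonnegative density values, one per row of `W`.
#' @export
density_eval <- function(g, a, W) {
  df <- as_learner_frame(W)
  n <- nrow(df)
  a <- rep_len(as.numeric(a), n)
  out <- numeric(n)
  inside <- a >= 0 & a <= 1
  if (!any(inside)) return(out)
  for (ci in seq_along(g$candidates)) {
    w <- g$weights[ci]
    if (w == 0) next
    cand <- g$candidates[[ci]]
    P <- hist_bin_probs(cand, df[inside, , drop = FALSE])
    widths <- diff(cand$edges)
    b <- bin_index(a[inside], cand$edges)
    out[inside] <- out[inside] + w * P[cbind(seq_len(sum(inside)), b)] / widths[b]
  }
  out
}

#' @export
predict.hist_density <- function(object, a, W, ...) density_eval(object, a, W)

#' @export
print.hist_density <- function(x, ...) {
  cat("Stacked histogram conditional density\n")
  tab <- data.frame(
    n_bins = vapply(x$specs, `[[`, integer(1), "n_bins"),
    placement = vapply(x$specs, `[[`, character(1), "placement"),
    weight = round(x$weights, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

# ---- internal: union-cell representation ------------------------------

# Union of all positively-weighted candidates' bin edges.
density_union_edges <- function(g) {
  edges <- sort(unique(unlist(lapply(which(g$weights > 0),
                                     function(ci) g$candidates[[ci]]$edges))))
  edges[c(TRUE, diff(edges) > 1e-10)]
}

# n x B matrix of mixture bin probabilities on the union cells; exact
# because each candidate's density is constant within its own bins, so its
# probability over a union cell is proportional to the cell width.
density_union_probs <- function(g, W, edges = density_union_edges(g)) {
  df <- as_learner_frame(W)
  n <- nrow(df)
  B <- length(edges) - 1L
  mids <- (edges[-1L] + edges[-(B + 1L)]) / 2
  widths <- diff(edges)
  P <- matrix(0, n, B)
  for (ci in seq_along(g$candidates)) {
    w <- g$weights[ci]
    if (w == 0) next
    cand <- g$candidates[[ci]]
    Pc <- hist_bin_probs(cand, df)
    cw <- diff(cand$edges)
    cb <- bin_index(mids, cand$edges)
    # spread candidate bin prob over the union cells it contains
    P <- P + w * Pc[, cb, drop = FALSE] *
      matrix(widths / cw[cb], n, B, byrow = TRUE)
  }
  P
}
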