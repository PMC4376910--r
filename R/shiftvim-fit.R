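#' Fit the shift-intervention variable importance measure
#'
#' The main fitting front-end: given a reduced cross-sectional problem
#' (covariates W, exposure observedness C, exposure A, binary outcome Y),
#' estimates the VIM \code{E(Y^I) - E(Y)} — the change in mean outcome if
#' every subject's continuous exposure were shifted up by `delta` (on the
#' \[0,1\] scale), or every subject's probability of a binary exposure were
#' raised by `delta` — with the requested estimators.
#'
#' Nuisances (outcome regression, exposure mechanism, missingness mechanism)
#' are fitted by the cross-validated super learner and, for continuous
#' exposures, the stacked histogram conditional density estimator; a
#' pre-built [nuisance_set()] (e.g. known truths in simulations) can be
#' supplied instead.  The Gcomp/IPMW and unadjusted estimators fit their own
#' stepwise-regression nuisances by construction.
#'
#' @param cs a [cross_section()], e.g. from [extract_cross_section()].
#' @param delta shift size (default 0.01, the reporting convention for
#'   \[0,1\]-rescaled variables).  For binary exposures `delta` must be
#'   smaller than the estimated minimum of g(0|1,w).
#' @param estimators subset of `c("tmle", "ee", "gcomp_ipmw", "unadjusted")`.
#' @param nuisances optional [nuisance_set()]; default: fitted via
#'   [fit_nuisances()].
#' @param sl_library super-learner candidates for the nuisance fits.
#' @param density_candidates histogram candidate grid for a continuous
#'   exposure, see [density_fit()].
#' @param V cross-validation folds.
#' @param alpha level for Wald intervals (default 0.05).
#' @param seed optional integer seed making the fit deterministic.
#' @param control numerical settings, see [shiftvim_control()].
#' @return An object of class `"shiftvim"`: list with `estimates` (named
#'   list of [vim_estimate()]s), `nuisances`, `positivity`, `delta`, `cs`
#'   metadata.  Methods: `print`, `summary`, `coef`, `confint`, `plot`.
#' @examples
#' d <- generate_worked_example(400, "worked_logistic", seed = 1)
#' fit <- shiftvim(d, delta = 0.01, sl_library = c("GLM", "MEAN"),
#'                 estimators = c("ee", "unadjusted"), seed = 1,
#'                 density_candidates = data.frame(n_bins = 5,
#'                                                 placement = "equal_width"))
#' summary(fit)
#' @export
shiftvim <- function(cs, delta = 0.01,
                     estimators = c("tmle", "ee", "gcomp_ipmw", "unadjusted"),
                     nuisances = NULL,
                     sl_library = sl_library_default(),
                     density_candidates = expand.grid(
                       n_bins = c(2L, 5L, 10L, 20L),
                       placement = c("equal_width", "equal_frequency"),
                       stringsAsFactors = FALSE),
                     V = 10L, alpha = 0.05, seed = NULL,
                     control = shiftvim_control()) {
  stopifnot(inherits(cs, "cross_section"), delta > 0)
  estimators <- match.arg(estimators, several.ok = TRUE)
  needs_nuis <- any(c("tmle", "ee") %in% estimators)
  if (needs_nuis && is.null(nuisances)) {
    nuisances <- fit_nuisances(cs, sl_library = sl_library, V = V,
                               seed = seed,
                               density_candidates = density_candidates)
  }
  positivity <- if (needs_nuis)
    positivity_check(nuisances, cs, delta, control) else NULL

  est <- list()
  for (e in estimators) {
    est[[e]] <- switch(e,
      tmle = vim_tmle(cs, nuisances, delta, alpha, control),
      ee = vim_ee(cs, nuisances, delta, alpha, control),
      gcomp_ipmw = vim_gcomp_ipmw(cs, delta, alpha, control),
      unadjusted = vim_unadjusted(cs, delta, alpha, control))
  }
  structure(list(estimates = est, nuisances = nuisances,
                 positivity = positivity, delta = delta, alpha = alpha,
                 kind = cs$exposure_kind, meta = cs$meta, n = cs$n),
            class = "shiftvim")
}

#' @export
print.shiftvim <- function(x, ...) {
  cat(sprintf("Shift-intervention VIM fit (%s exposure, delta = %g, n = %d)\n",
              x$kind, x$delta, x$n))
  print(summary(x))
  invisible(x)
}

#' @export
summary.shiftvim <- function(object, ...) {
  rows <- lapply(object$estimates, function(e)
    data.frame(estimator = e$estimator, psi = e$psi, se = e$se,
               ci_lower = e$ci[1], ci_upper = e$ci[2],
               p_value = e$p_value))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.shiftvim", "data.frame")
  out
}

#' @export
print.summary.shiftvim <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "data.frame"
  y$psi <- round(y$psi, digits)
  y$se <- round(y$se, digits)
  y$ci_lower <- round(y$ci_lower, digits)
  y$ci_upper <- round(y$ci_upper, digits)
  y$p_value <- vapply(y$p_value, format_pval, character(1))
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.shiftvim <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "psi")
}

#' @export
confint.shiftvim <- function(object, parm, level = 0.95, ...) {
  out <- t(vapply(object$estimates, `[[`, numeric(2), "ci"))
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' @export
plot.shiftvim <- function(x, ...) {
  s <- summary(x)
  k <- nrow(s)
  ylim <- range(c(s$ci_lower, s$ci_upper, 0))
  plot(seq_len(k), s$psi, ylim = ylim, xaxt = "n", pch = 19,
       xlab = "", ylab = expression(hat(psi)),
       main = sprintf("Shift VIM (delta = %g)", x$delta), ...)
  graphics::axis(1, at = seq_len(k), labels = s$estimator)
  graphics::segments(seq_len(k), s$ci_lower, seq_len(k), s$ci_upper)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
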