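# End-to-end orchestration: loop over outcome intervals and treatment
# variables, extract cross-sections, fit all requested estimators, and
# produce significance-filtered ranked VIM tables.

#' Run a full variable-importance study
#'
#' For each outcome interval \code{j'} and each treatment variable measured
#' at a time \code{j <= j'}, extracts the cross-sectional problem, fits
#' nuisances, and runs the requested estimators.  Cells that fail or are
#' degenerate (constant exposure, empty at-risk set, one-class outcome) are
#' skipped with the reason logged in the returned object.  Deterministic
#' given \code{seed}: each cell uses a seed derived from \code{(seed, k, j,
#' j')}, so results do not depend on the order in which cells are run.
#'
#' @param data a [longitudinal_data()] object.
#' @param delta shift size (default 0.01, the reporting convention).
#' @param alpha significance level (default 0.05).
#' @param estimators estimator subset, see [shiftvim()].
#' @param sl_library,density_candidates,V nuisance settings, see
#'   [shiftvim()].
#' @param seed integer seed.
#' @param history adjustment-set convention, see [extract_cross_section()].
#' @param control numerical settings, see [shiftvim_control()].
#' @param verbose print per-cell progress lines.
#' @return Object of class `"vim_study"`: list with `estimates` (long data
#'   frame: variable, k, j, j_prime, n, estimator, psi, se, ci bounds,
#'   p_value), `fits` (per-cell [shiftvim()] objects, named "k<k>_j<j>_jp<j'>"),
#'   `failures` (data frame of skipped cells and reasons), and the
#'   configuration.  Methods: `print`, `summary`.
#' @export
run_study <- function(data, delta = 0.01, alpha = 0.05,
                      estimators = c("tmle", "ee", "gcomp_ipmw", "unadjusted"),
                      sl_library = sl_library_default(),
                      density_candidates = expand.grid(
                        n_bins = c(2L, 5L, 10L, 20L),
                        placement = c("equal_width", "equal_frequency"),
                        stringsAsFactors = FALSE),
                      V = 10L, seed = NULL,
                      history = c("markov", "full"),
                      control = shiftvim_control(), verbose = FALSE) {
  stopifnot(inherits(data, "longitudinal_data"))
  history <- match.arg(history)
  treat <- which(data$var_meta$role == "treatment")
  cells <- expand.grid(k = treat, j = seq_len(data$J),
                       j_prime = seq_len(data$J))
  cells <- cells[cells$j <= cells$j_prime, , drop = FALSE]
  cells <- cells[order(cells$j_prime, cells$j, cells$k), , drop = FALSE]

  rows <- list(); fits <- list(); fails <- list()
  for (r in seq_len(nrow(cells))) {
    k <- cells$k[r]; j <- cells$j[r]; jp <- cells$j_prime[r]
    tag <- sprintf("k%d_j%d_jp%d", k, j, jp)
    res <- tryCatch({
      cs <- extract_cross_section(data, k, j, jp, history = history)
      a_obs <- cs$A[cs$C == 1]
      if (length(a_obs) < 2L || length(unique(a_obs)) < 2L)
        stop("degenerate cell: exposure constant or unobserved")
      if (length(unique(cs$Y)) < 2L)
        stop("degenerate cell: one-class outcome")
      cell_seed <- if (is.null(seed)) NULL else derive_seed(seed, k, j, jp)
      shiftvim(cs, delta = delta, estimators = estimators,
               sl_library = sl_library,
               density_candidates = density_candidates, V = V,
               alpha = alpha, seed = cell_seed, control = control)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[tag]] <- conditionMessage(res)
      if (verbose) message(sprintf("[%s] skipped: %s", tag, fails[[tag]]))
      next
    }
    fits[[tag]] <- res
    s <- summary(res)
    rows[[tag]] <- cbind(
      data.frame(variable = data$var_meta$name[k], k = k, j = j,
                 j_prime = jp, n = res$n, stringsAsFactors = FALSE), s)
    if (verbose) message(sprintf("[%s] done (n = %d)", tag, res$n))
  }
  estimates <- if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL
    class(out) <- "data.frame"
    out
  } else {
    data.frame(variable = character(), k = integer(), j = integer(),
               j_prime = integer(), n = integer(), estimator = character(),
               psi = numeric(), se = numeric(), ci_lower = numeric(),
               ci_upper = numeric(), p_value = numeric())
  }
  failures <- data.frame(cell = names(fails),
                         reason = unlist(fails, use.names = FALSE),
                         stringsAsFactors = FALSE)
  structure(list(estimates = estimates, fits = fits, failures = failures,
                 delta = delta, alpha = alpha, estimators = estimators,
                 seed = seed, var_meta = data$var_meta, J = data$J),
            class = "vim_study")
}

#' @export
print.vim_study <- function(x, ...) {
  cat(sprintf("VIM study: delta = %g, alpha = %g, %d cells fitted, %d skipped\n",
              x$delta, x$alpha, length(x$fits), nrow(x$failures)))
  if (nrow(x$failures)) {
    cat("skipped cells:\n")
    for (i in seq_len(nrow(x$failures)))
      cat(sprintf("  %s: %s\n", x$failures$cell[i], x$failures$reason[i]))
  }
  invisible(x)
}

#' @export
summary.vim_study <- function(object, top = 5L, ...) {
  rank_vims(object$estimates, alpha = object$alpha, top = top)
}

#' Rank significant variable importances per outcome interval
#'
#' Keeps the variables whose TMLE p-value is below \code{alpha} (the
#' significance filter is applied to the TMLE column; all requested
#' estimator columns are reported for the kept rows), ranks them by the
#' magnitude of the TMLE estimate, and returns at most \code{top} rows per
#' outcome interval.  Signs are retained; ordering applies to \code{|psi|}.
#'
#' @param estimates long-format estimates data frame from [run_study()]
#'   (columns variable, k, j, j_prime, estimator, psi, se, p_value), or a
#'   `"vim_study"` object.
#' @param alpha significance level for the filter.
#' @param top maximum rows reported per interval.
#' @param order `"decreasing"` (most important first, default) or
#'   `"increasing"`.
#' @return Data frame: j_prime, rank, variable, j, n, then `psi_<est>`,
#'   `se_<est>`, `p_<est>` column triples for each estimator present.
#' @export
rank_vims <- function(estimates, alpha = 0.05, top = 5L,
                      order = c("decreasing", "increasing")) {
  order <- match.arg(order)
  if (inherits(estimates, "vim_study")) estimates <- estimates$estimates
  stopifnot(is.data.frame(estimates))
  empty <- data.frame(j_prime = integer(), rank = integer(),
                      variable = character(), j = integer(), n = integer())
  if (!nrow(estimates)) return(empty)
  if (!"tmle" %in% estimates$estimator)
    stop("ranking requires TMLE estimates (the significance filter)")

  ests <- unique(estimates$estimator)
  key <- function(d) paste(d$k, d$j, d$j_prime, sep = "|")
  wide_rows <- list()
  for (jp in sort(unique(estimates$j_prime))) {
    sub <- estimates[estimates$j_prime == jp, , drop = FALSE]
    tm <- sub[sub$estimator == "tmle", , drop = FALSE]
    tm <- tm[!is.na(tm$p_value) & tm$p_value < alpha, , drop = FALSE]
    if (!nrow(tm)) next
    o <- base::order(abs(tm$psi), decreasing = (order == "decreasing"))
    tm <- tm[o, , drop = FALSE]
    tm <- utils::head(tm, top)
    for (i in seq_len(nrow(tm))) {
      row <- data.frame(j_prime = jp, rank = i, variable = tm$variable[i],
                        j = tm$j[i], n = tm$n[i], stringsAsFactors = FALSE)
      for (e in ests) {
        m <- sub[sub$estimator == e & key(sub) == key(tm[i, ]), , drop = FALSE]
        lab <- tolower(gsub("[^A-Za-z]", "", e))
        row[[paste0("psi_", lab)]] <- if (nrow(m)) m$psi[1] else NA_real_
        row[[paste0("se_", lab)]] <- if (nrow(m)) m$se[1] else NA_real_
        row[[paste0("p_", lab)]] <- if (nrow(m)) m$p_value[1] else NA_real_
      }
      wide_rows[[length(wide_rows) + 1L]] <- row
    }
  }
  if (!length(wide_rows)) return(empty)
  out <- do.call(rbind, wide_rows)
  rownames(out) <- NULL
  out
}

#' Write a ranked VIM table as TSV
#'
#' Serializes a [rank_vims()] table with estimates rounded to 4 decimals and
#' p-values formatted to 3 decimals, floored at 0.001 (printed as
#' `< 0.001`).
#'
#' @param ranked data frame from [rank_vims()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_vim_table <- function(ranked, path) {
  out <- ranked
  for (nm in names(out)) {
    if (startsWith(nm, "psi_") || startsWith(nm, "se_"))
      out[[nm]] <- round(out[[nm]], 4)
    if (startsWith(nm, "p_"))
      out[[nm]] <- vapply(out[[nm]], format_pval, character(1))
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the full (unfiltered) estimates table as TSV
#'
#' @param study a `"vim_study"` object or its long estimates data frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_estimates_table <- function(study, path) {
  est <- if (inherits(study, "vim_study")) study$estimates else study
  out <- est
  out$psi <- round(out$psi, 6)
  out$se <- round(out$se, 6)
  out$ci_lower <- round(out$ci_lower, 6)
  out$ci_upper <- round(out$ci_upper, 6)
  out$p_value <- vapply(out$p_value, format_pval, character(1))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
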