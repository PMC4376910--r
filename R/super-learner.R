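# Cross-validated convex stacking ("super learner") for binary-outcome
# nuisance regressions.  The candidate library mirrors the six algorithms
# used throughout: main-terms logistic (GLM), AIC-based bidirectional
# stepwise logistic (SW), weakly ridge-penalised logistic standing in for
# Bayesian logistic regression (BGLM), smooth additive logistic (GAM, via
# mgcv), adaptive hinge-basis logistic regression (MARS), and the sample
# mean (MEAN).

# ---- fold construction -------------------------------------------------

# V-fold assignment, stratified on a binary y so no fold loses a class.
make_folds <- function(y, V, stratify = TRUE) {
  n <- length(y)
  folds <- integer(n)
  if (stratify && is_binary01(y) && length(unique(y)) == 2L) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(V), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(V), n))
  }
  folds
}

# ---- candidate learners ------------------------------------------------

fit_glm_main <- function(df, y) {
  stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial(),
             control = list(maxit = 50L))
}
predict_glm_like <- function(fit, df) {
  as.numeric(stats::predict(fit, newdata = df, type = "response"))
}

fit_stepwise <- function(df, y) {
  full <- fit_glm_main(df, y)
  stats::step(full, scope = list(lower = ~1, upper = stats::formula(full)),
              direction = "both", trace = 0)
}

# Ridge-penalised logistic regression via IRLS; a weak quadratic penalty on
# the non-intercept coefficients (lambda on [0,1]-scaled inputs).
fit_ridge_logit <- function(df, y, lambda = 0.1, maxit = 50L) {
  X <- cbind(`(Intercept)` = 1, as.matrix(df))
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  beta[1L] <- stats::qlogis(clip_prob(mean(y), 1e-4))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    H <- crossprod(X, X * w) + pen
    score <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-9) break
  }
  structure(list(beta = beta, cols = colnames(df)), class = "svim_ridge")
}
predict_ridge_logit <- function(fit, df) {
  X <- cbind(1, as.matrix(df[, fit$cols, drop = FALSE]))
  as.numeric(stats::plogis(drop(X %*% fit$beta)))
}

fit_gam_smooth <- function(df, y) {
  terms <- vapply(names(df), function(v) {
    nu <- length(unique(df[[v]]))
    if (nu >= 10L) sprintf("s(%s, k = %d)", v, min(5L, nu - 1L)) else v
  }, character(1))
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  mgcv::gam(f, data = cbind(df, y = y), family = stats::binomial(),
            method = "REML")
}

# Forward-selection hinge-basis ("MARS"-style) logistic regression.  At each
# step the reflected hinge pair max(x - t, 0), max(t - x, 0) with the best
# AIC improvement is added; selection stops when AIC no longer improves or
# max_terms basis functions are reached.
fit_mars_logit <- function(df, y, max_terms = 14L, n_knots = 5L) {
  n <- nrow(df)
  cand <- list()
  for (v in names(df)) {
    x <- df[[v]]
    ux <- unique(x)
    if (length(ux) <= 3L) {
      cand[[length(cand) + 1L]] <- list(var = v, knot = NA_real_)
      next
    }
    knots <- unique(stats::quantile(x, probs = seq_len(n_knots) / (n_knots + 1),
                                    names = FALSE, type = 7))
    for (t in knots) cand[[length(cand) + 1L]] <- list(var = v, knot = t)
  }
  basis_cols <- function(term, data) {
    x <- data[[term$var]]
    if (is.na(term$knot)) return(matrix(x, ncol = 1L))
    cbind(pmax(x - term$knot, 0), pmax(term$knot - x, 0))
  }
  Xcur <- matrix(1, n, 1L)
  terms <- list()
  fit <- stats::glm.fit(Xcur, y, family = stats::binomial())
  best_aic <- fit$aic
  repeat {
    if (ncol(Xcur) - 1L >= max_terms || !length(cand)) break
    trial_aic <- vapply(cand, function(term) {
      Xt <- cbind(Xcur, basis_cols(term, df))
      ft <- tryCatch(stats::glm.fit(Xt, y, family = stats::binomial(),
                                    control = list(maxit = 40L)),
                     error = function(e) NULL,
                     warning = function(w) suppressWarnings(
                       stats::glm.fit(Xt, y, family = stats::binomial(),
                                      control = list(maxit = 40L))))
      if (is.null(ft) || !is.finite(ft$aic)) Inf else ft$aic
    }, numeric(1))
    j <- which.min(trial_aic)
    if (!is.finite(trial_aic[j]) || trial_aic[j] >= best_aic - 1e-8) break
    terms[[length(terms) + 1L]] <- cand[[j]]
    Xcur <- cbind(Xcur, basis_cols(cand[[j]], df))
    best_aic <- trial_aic[j]
    cand[[j]] <- NULL
  }
  final <- suppressWarnings(stats::glm.fit(Xcur, y, family = stats::binomial(),
                                           control = list(maxit = 60L)))
  structure(list(terms = terms, beta = final$coefficients), class = "svim_mars")
}
predict_mars_logit <- function(fit, df) {
  X <- matrix(1, nrow(df), 1L)
  for (term in fit$terms) {
    x <- df[[term$var]]
    X <- if (is.na(term$knot)) cbind(X, x) else
      cbind(X, pmax(x - term$knot, 0), pmax(term$knot - x, 0))
  }
  beta <- fit$beta
  beta[is.na(beta)] <- 0
  as.numeric(stats::plogis(drop(X %*% beta)))
}

.sl_candidates <- list(
  GLM  = list(fit = fit_glm_main, predict = predict_glm_like),
  SW   = list(fit = fit_stepwise, predict = predict_glm_like),
  BGLM = list(fit = fit_ridge_logit, predict = predict_ridge_logit),
  GAM  = list(fit = fit_gam_smooth, predict = predict_glm_like),
  MARS = list(fit = fit_mars_logit, predict = predict_mars_logit),
  MEAN = list(fit = function(df, y) structure(list(p = mean(y)), class = "svim_mean"),
              predict = function(fit, df) rep(fit$p, nrow(df)))
)

#' Names of the built-in super-learner candidates
#' @return Character vector of candidate names.
#' @export
sl_library_default <- function() names(.sl_candidates)

# ---- stacking ----------------------------------------------------------

#' Fit a cross-validated convex stack of binary-outcome learners
#'
#' V-fold cross-validated predictions are computed for each candidate; the
#' stacking weights minimise the cross-validated risk of the convex
#' combination over the probability simplex (negative Bernoulli
#' log-likelihood by default, squared error optionally).  Candidates are then
#' refit on the full data.  Candidates that fail on any fold are dropped with
#' a warning.  A degenerate outcome (all 0 or all 1) returns a MEAN-only fit
#' with a warning.
#'
#' @param X covariate matrix or data.frame.
#' @param y binary 0/1 response.
#' @param library character vector of candidate names (subset of
#'   [sl_library_default()]).
#' @param V number of folds (default 10), stratified on `y`.
#' @param seed optional integer; fold assignment (and hence the fit) is
#'   deterministic given the seed and data.
#' @param loss `"nll"` (negative Bernoulli log-likelihood, default) or
#'   `"mse"`.
#' @return Object of class `"sl_fit"` with elements `weights`, `candidates`
#'   (full-data fits), `cv_risks` (per candidate and `ensemble`), `folds`.
#' @examples
#' set.seed(1)
#' X <- matrix(runif(200), ncol = 2)
#' y <- rbinom(100, 1, plogis(X[, 1] - X[, 2]))
#' fit <- sl_fit(X, y, library = c("GLM", "MEAN"), V = 5, seed = 1)
#' fit$weights
#' @export
sl_fit <- function(X, y, library = sl_library_default(), V = 10L,
                   seed = NULL, loss = c("nll", "mse")) {
  loss <- match.arg(loss)
  df <- as_learner_frame(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(df) == n, is_binary01(y))
  if (!length(library)) stop("need at least one candidate")
  unknown <- setdiff(library, names(.sl_candidates))
  if (length(unknown)) stop("unknown candidates: ", paste(unknown, collapse = ", "))
  if (n < V) stop("need n >= V")

  if (length(unique(y)) < 2L) {
    warning("degenerate outcome (constant y): returning MEAN-only fit")
    library <- "MEAN"
  }

  folds <- with_seed(seed, make_folds(y, V))
  k <- length(library)
  Z <- matrix(NA_real_, n, k, dimnames = list(NULL, library))
  ok <- rep(TRUE, k)
  for (ci in seq_len(k)) {
    cand <- .sl_candidates[[library[ci]]]
    for (v in seq_len(V)) {
      test <- folds == v
      fit_v <- tryCatch(
        suppressWarnings(cand$fit(df[!test, , drop = FALSE], y[!test])),
        error = function(e) NULL)
      if (is.null(fit_v)) { ok[ci] <- FALSE; break }
      pred <- tryCatch(
        suppressWarnings(cand$predict(fit_v, df[test, , drop = FALSE])),
        error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) { ok[ci] <- FALSE; break }
      Z[test, ci] <- pred
    }
    if (!ok[ci])
      warning("candidate ", library[ci], " failed in cross-validation; dropped")
  }
  if (!any(ok)) stop("all super-learner candidates failed")
  library <- library[ok]
  Z <- Z[, ok, drop = FALSE]
  Z <- clip_prob(Z)

  risk_of <- if (loss == "nll") {
    function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    function(p) mean((y - p)^2)
  }
  weights <- optimize_simplex_weights(function(w) risk_of(clip_prob(drop(Z %*% w))),
                                      ncol(Z))
  cv_risks <- c(vapply(seq_len(ncol(Z)), function(j) risk_of(Z[, j]), numeric(1)),
                ensemble = risk_of(clip_prob(drop(Z %*% weights))))
  names(cv_risks) <- c(library, "ensemble")

  full_fits <- lapply(library, function(nm)
    suppressWarnings(.sl_candidates[[nm]]$fit(df, y)))
  names(full_fits) <- library

  structure(list(weights = stats::setNames(weights, library),
                 candidates = full_fits, cv_risks = cv_risks,
                 library = library, folds = list(V = V, seed = seed,
                                                 assignment = folds),
                 loss = loss, train_cols = names(df)),
            class = "sl_fit")
}

#' Predict from a super-learner stack
#'
#' Convex combination of the candidate predictions, clipped to
#' \code{[1e-6, 1 - 1e-6]} for downstream logit transforms.
#'
#' @param object an [sl_fit()] object.
#' @param newdata covariate matrix with the training columns.
#' @param ... unused.
#' @return Probability vector.
#' @export
predict.sl_fit <- function(object, newdata, ...) {
  df <- as_learner_frame(newdata)
  if (!identical(names(df), object$train_cols))
    stop("newdata columns do not match the training matrix")
  p <- numeric(nrow(df))
  for (nm in object$library) {
    w <- object$weights[[nm]]
    if (w == 0) next
    p <- p + w * .sl_candidates[[nm]]$predict(object$candidates[[nm]], df)
  }
  clip_prob(p)
}

#' @rdname predict.sl_fit
#' @param fit an [sl_fit()] object.
#' @param X_new covariate matrix.
#' @export
sl_predict <- function(fit, X_new) predict(fit, X_new)

#' @export
print.sl_fit <- function(x, ...) {
  cat("Super-learner stack (", x$loss, " loss)\n", sep = "")
  tab <- data.frame(candidate = names(x$weights),
                    weight = round(unname(x$weights), 4),
                    cv_risk = round(unname(x$cv_risks[names(x$weights)]), 5))
  print(tab, row.names = FALSE)
  cat(sprintf("ensemble CV risk: %.5f\n", x$cv_risks[["ensemble"]]))
  invisible(x)
}

#' Write the per-fit super-learner diagnostic table
#'
#' TSV with one row per candidate: name, cross-validated risk, weight.
#'
#' @param fit an [sl_fit()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sl_report <- function(fit, path) {
  tab <- data.frame(candidate = names(fit$weights),
                    cv_risk = unname(fit$cv_risks[names(fit$weights)]),
                    weight = unname(fit$weights))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
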