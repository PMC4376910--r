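# Cross-validated prediction diagnostics: out-of-fold predictions for the
# super learner and the stepwise benchmark on a shared fold partition, and
# ROC/AUC by the rank (concordance) formula.

#' Out-of-fold cross-validated predictions
#'
#' Every prediction is produced by a model fit with that observation's fold
#' held out.  The fold partition depends only on \code{(y, V, seed)}, so
#' calling with the same seed for different learners compares them on
#' identical folds.  A learner that fails on a fold leaves `NA` predictions
#' for that fold, with a warning.
#'
#' @param X covariate matrix or data frame.
#' @param y binary outcome vector.
#' @param learner `"super_learner"` or `"stepwise"` (AIC-based
#'   bidirectional stepwise logistic regression).
#' @param V folds (default 10, stratified on `y`).
#' @param seed integer seed controlling the fold partition (and the super
#'   learner's internal CV).
#' @param sl_library candidate set for the super learner.
#' @return List with `pred` (out-of-fold probabilities, `NA` on failed
#'   folds), `folds` (fold assignment), `learner`.
#' @export
cv_predictions <- function(X, y, learner = c("super_learner", "stepwise"),
                           V = 10L, seed = NULL,
                           sl_library = sl_library_default()) {
  learner <- match.arg(learner)
  stopifnot(length(y) >= V, V >= 2L)
  df <- as_learner_frame(X)
  stopifnot(nrow(df) == length(y))
  folds <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 97L),
                     make_folds(y, V, stratify = TRUE))
  pred <- rep(NA_real_, length(y))
  for (v in seq_len(V)) {
    hold <- folds == v
    fit <- tryCatch({
      if (learner == "super_learner") {
        sl_fit(df[!hold, , drop = FALSE], y[!hold], library = sl_library,
               V = V, seed = if (is.null(seed)) NULL
               else derive_seed(seed, 131L, v))
      } else {
        fit_stepwise_or_main(df[!hold, , drop = FALSE], y[!hold])
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("fold %d: %s fit failed (%s); predictions set to NA",
                      v, learner, conditionMessage(fit)))
      next
    }
    p <- if (learner == "super_learner")
      predict(fit, df[hold, , drop = FALSE])
    else as.numeric(stats::predict(fit, newdata = df[hold, , drop = FALSE],
                                   type = "response"))
    pred[hold] <- p
  }
  list(pred = pred, folds = folds, learner = learner)
}

#' ROC curve and AUC
#'
#' AUC by the rank/concordance formula — the proportion of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counted one half.  The ROC is the full step curve over all distinct
#' score thresholds.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return Object of class `"roc_auc"`: list with `auc` and `roc` (data
#'   frame: threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  if (!is_binary01(labels) || length(unique(labels)) < 2L)
    stop("AUC undefined: labels must contain both classes")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  structure(list(auc = auc,
                 roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "roc_auc")
}

#' @export
print.roc_auc <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC = %.4f\n", nrow(x$roc), x$auc))
  invisible(x)
}

#' @export
plot.roc_auc <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Write ROC points as TSV
#'
#' @param x a `"roc_auc"` object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_roc_points <- function(x, path) {
  stopifnot(inherits(x, "roc_auc"))
  utils::write.table(x$roc[, c("fpr", "tpr", "threshold")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
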