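# Plain-text readers and writers for the long-format study layout.

#' Read a long-format longitudinal study CSV
#'
#' Expected columns: \code{subject_id}, \code{time}, one column per variable,
#' one \code{<var>_observed} flag column per longitudinal variable, and
#' \code{death} (the interval death indicator attached to the row's time
#' point).  Baseline variables (role \code{"baseline"} in the metadata) are
#' taken from each subject's first row and need no flag column.
#'
#' @param path CSV file path.
#' @param meta_path path to the variable metadata file, see
#'   [read_var_meta()].
#' @param rescale if \code{TRUE} (default), continuous variables are mapped
#'   to \code{[0,1]} with [rescale_unit_interval()]; constant variables are
#'   dropped with a warning.
#' @return A [longitudinal_data()] object.
#' @export
read_longitudinal_csv <- function(path, meta_path, rescale = TRUE) {
  meta <- read_var_meta(meta_path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "time", "death") %in% names(df)))
  df <- df[order(df$subject_id, df$time), ]
  ids <- unique(df$subject_id)
  times <- sort(unique(df$time))
  n <- length(ids); J <- length(times)

  base_meta <- meta[meta$role == "baseline", , drop = FALSE]
  long_meta <- meta[meta$role == "treatment", , drop = FALSE]
  K <- nrow(long_meta)
  if (K == 0L) stop("metadata declares no treatment (longitudinal) variables")
  missing_cols <- setdiff(c(base_meta$name, long_meta$name,
                            paste0(long_meta$name, "_observed")), names(df))
  if (length(missing_cols))
    stop("CSV lacks columns: ", paste(missing_cols, collapse = ", "))

  first <- df[!duplicated(df$subject_id), , drop = FALSE]
  baseline <- as.matrix(first[, base_meta$name, drop = FALSE])
  rownames(baseline) <- NULL

  covs <- array(NA_real_, dim = c(n, J, K))
  flags <- array(0, dim = c(n, J, K))
  death <- matrix(NA_real_, n, J)
  row_i <- match(df$subject_id, ids)
  row_j <- match(df$time, times)
  for (k in seq_len(K)) {
    v <- long_meta$name[k]
    covs[cbind(row_i, row_j, k)] <- df[[v]]
    flags[cbind(row_i, row_j, k)] <- df[[paste0(v, "_observed")]]
  }
  death[cbind(row_i, row_j)] <- df$death
  flags[is.na(flags)] <- 0
  covs[flags == 0] <- NA_real_

  if (rescale) {
    keep <- rep(TRUE, K)
    for (k in seq_len(K)) {
      if (long_meta$kind[k] != "continuous") next
      vals <- covs[, , k]
      sc <- try(rescale_unit_interval(as.numeric(vals)), silent = TRUE)
      if (inherits(sc, "try-error")) {
        warning("dropping degenerate variable ", long_meta$name[k])
        keep[k] <- FALSE
      } else {
        covs[, , k] <- matrix(as.numeric(sc), n, J)
      }
    }
    covs <- covs[, , keep, drop = FALSE]
    flags <- flags[, , keep, drop = FALSE]
    long_meta <- long_meta[keep, , drop = FALSE]
    for (b in seq_len(ncol(baseline))) {
      if (base_meta$kind[b] == "continuous")
        baseline[, b] <- as.numeric(rescale_unit_interval(baseline[, b]))
    }
  }

  longitudinal_data(baseline = baseline, covariates = covs,
                    miss_flags = flags, death = death, times = times,
                    var_meta = long_meta[, c("name", "kind", "role")],
                    subject_id = ids)
}

#' Read a variable metadata file
#'
#' Whitespace- or comma-separated text with a header and columns
#' \code{name}, \code{kind} (\code{continuous}/\code{binary}) and \code{role}
#' (\code{baseline}/\code{treatment}).
#'
#' @param path file path.
#' @return data.frame with columns name, kind, role.
#' @export
read_var_meta <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- if (grepl(",", first)) {
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "kind", "role") %in% names(meta)))
  meta
}

#' Write a longitudinal study to long-format CSV + metadata
#'
#' Inverse of [read_longitudinal_csv()]; used by the `simulate` command-line
#' entry point.
#'
#' @param data a [longitudinal_data()] object.
#' @param path CSV output path.
#' @param meta_path metadata output path.
#' @return Invisibly, the paths written.
#' @export
write_longitudinal_csv <- function(data, path, meta_path) {
  n <- data$n; J <- data$J; K <- data$K
  rows <- expand.grid(i = seq_len(n), j = seq_len(J))
  df <- data.frame(subject_id = data$subject_id[rows$i],
                   time = data$times[rows$j])
  for (b in seq_len(ncol(data$baseline)))
    df[[colnames(data$baseline)[b]]] <- data$baseline[rows$i, b]
  for (k in seq_len(K)) {
    v <- data$var_meta$name[k]
    df[[v]] <- data$covariates[cbind(rows$i, rows$j, k)]
    df[[paste0(v, "_observed")]] <- data$miss_flags[cbind(rows$i, rows$j, k)]
  }
  df$death <- data$death[cbind(rows$i, rows$j)]
  utils::write.csv(df, path, row.names = FALSE)
  base_meta <- data.frame(name = colnames(data$baseline),
                          kind = ifelse(apply(data$baseline, 2, is_binary01),
                                        "binary", "continuous"),
                          role = "baseline")
  meta <- rbind(base_meta, data$var_meta[, c("name", "kind", "role")])
  utils::write.table(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, meta_path))
}

#' Write an extracted cross-section as TSV for audit
#'
#' @param cs a [cross_section()] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cross_section <- function(cs, path) {
  df <- data.frame(C = cs$C, A = cs$A, Y = cs$Y)
  df <- cbind(df, as.data.frame(cs$W))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
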