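#' Longitudinal study container
#'
#' Bundles the observed data structure of a discrete-time longitudinal study
#' with missing covariates: baseline covariates \code{L0}, longitudinal
#' covariates \code{L[j,k]} measured on an ordered time grid, per-covariate
#' missingness indicators \code{C[j,k]} (1 = observed), and an interval death
#' indicator \code{Y[j] = I(t_j < T <= t_{j+1})} (the last interval is
#' open-ended, \code{t_{J+1} = Inf}; ties at an interval boundary resolve to
#' the earlier interval).  Time points are indexed \code{j = 1..J} in R
#' convention with \code{t_1 = 0} the admission time.
#'
#' Invariants enforced: a longitudinal covariate value is present iff its
#' missingness flag is 1; death is absorbing (entries after the death interval
#' are ignored and stored as \code{NA}); continuous covariates lie in
#' \code{[0,1]} (rescale first, see [rescale_unit_interval()]) and binary
#' covariates in \code{{0,1}}.
#'
#' @param baseline numeric matrix or data.frame (n x p0) of baseline
#'   covariates, assumed complete.
#' @param covariates numeric array (n x J x K) of longitudinal covariates;
#'   \code{NA} where unobserved.
#' @param miss_flags 0/1 array (n x J x K); 1 = observed.
#' @param death 0/1 matrix (n x J); \code{death[i, j] = 1} if subject i dies
#'   in interval j.  Entries after a death may be \code{NA}.
#' @param times numeric vector of the J measurement times, strictly
#'   increasing, starting at 0.
#' @param var_meta data.frame with columns \code{name}, \code{kind}
#'   (\code{"continuous"} or \code{"binary"}) and \code{role}
#'   (\code{"baseline"} or \code{"treatment"}) for the K longitudinal
#'   variables.
#' @param subject_id optional vector of subject identifiers.
#'
#' @return An object of class \code{"longitudinal_data"}.
#' @seealso [extract_cross_section()], [read_longitudinal_csv()]
#' @export
longitudinal_data <- function(baseline, covariates, miss_flags, death, times,
                              var_meta, subject_id = NULL) {
  baseline <- as.matrix(baseline)
  storage.mode(baseline) <- "double"
  if (is.null(colnames(baseline)))
    colnames(baseline) <- paste0("L0_", seq_len(ncol(baseline)))
  covariates <- as.array(covariates)
  miss_flags <- as.array(miss_flags)
  death <- as.matrix(death)
  stopifnot(length(dim(covariates)) == 3L,
            all(dim(covariates) == dim(miss_flags)))
  n <- dim(covariates)[1L]
  J <- dim(covariates)[2L]
  K <- dim(covariates)[3L]
  stopifnot(nrow(baseline) == n, nrow(death) == n, ncol(death) == J,
            length(times) == J, !is.unsorted(times, strictly = TRUE))
  if (!is.data.frame(var_meta) ||
      !all(c("name", "kind", "role") %in% names(var_meta)) ||
      nrow(var_meta) != K)
    stop("`var_meta` must be a data.frame with columns name/kind/role, one row per variable")
  stopifnot(all(var_meta$kind %in% c("continuous", "binary")),
            all(var_meta$role %in% c("baseline", "treatment")))
  if (is.null(subject_id)) subject_id <- seq_len(n)

  # observed iff flag = 1
  if (any(is.na(miss_flags)) || !all(miss_flags %in% c(0, 1)))
    stop("miss_flags must be 0/1 with no NAs")
  obs <- miss_flags == 1
  if (any(is.na(covariates[obs])))
    stop("covariate marked observed (flag 1) but value is NA")
  covariates[!obs] <- NA_real_

  # value-range invariants per variable kind
  for (k in seq_len(K)) {
    vals <- covariates[, , k][obs[, , k]]
    if (var_meta$kind[k] == "binary" && !is_binary01(vals))
      stop(sprintf("variable %s declared binary but has non-0/1 values",
                   var_meta$name[k]))
    if (var_meta$kind[k] == "continuous" &&
        any(vals < 0 | vals > 1, na.rm = TRUE))
      stop(sprintf("continuous variable %s outside [0,1]; rescale first",
                   var_meta$name[k]))
  }

  # absorbing death: blank everything after the death interval
  for (i in seq_len(n)) {
    dj <- which(death[i, ] == 1)
    if (length(dj)) {
      dj <- dj[1L]
      if (dj < J) {
        death[i, (dj + 1L):J] <- NA
        covariates[i, (dj + 1L):J, ] <- NA
        miss_flags[i, (dj + 1L):J, ] <- 0
      }
      death[i, dj] <- 1
    }
  }
  structure(list(baseline = baseline, covariates = covariates,
                 miss_flags = miss_flags, death = death, times = times,
                 var_meta = var_meta, subject_id = subject_id,
                 n = n, J = J, K = K),
            class = "longitudinal_data")
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat("Longitudinal study data\n")
  cat(sprintf("  subjects: %d, time points: %d, longitudinal variables: %d\n",
              x$n, x$J, x$K))
  cat(sprintf("  baseline covariates: %d\n", ncol(x$baseline)))
  cat(sprintf("  deaths per interval: %s\n",
              paste(colSums(x$death == 1, na.rm = TRUE), collapse = " ")))
  obs_rate <- mean(x$miss_flags == 1)
  cat(sprintf("  overall observation rate: %.3f\n", obs_rate))
  invisible(x)
}

#' Rescale a numeric vector to the unit interval
#'
#' Applies \code{(x - min) / (max - min)} using observed entries only, so the
#' observed minimum maps to 0 and the maximum to 1.  Missing entries stay
#' missing.  The offset and range are kept as attributes so the mapping can be
#' inverted with [unrescale_unit_interval()].
#'
#' @param x numeric vector, possibly with \code{NA}s.
#' @return Rescaled vector with attributes \code{offset} and \code{range}.
#' @export
rescale_unit_interval <- function(x) {
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2L)
    stop("degenerate variable: fewer than 2 distinct observed values (zero range)")
  lo <- min(obs)
  rg <- max(obs) - lo
  out <- (x - lo) / rg
  attr(out, "offset") <- lo
  attr(out, "range") <- rg
  out
}

#' Invert a unit-interval rescaling
#'
#' @param x vector produced by [rescale_unit_interval()] (or any vector, with
#'   explicit `offset`/`range`).
#' @param offset,range the original minimum and range; default: taken from
#'   the attributes of `x`.
#' @return Vector on the original scale.
#' @export
unrescale_unit_interval <- function(x, offset = attr(x, "offset"),
                                    range = attr(x, "range")) {
  if (is.null(offset) || is.null(range))
    stop("offset/range not available")
  as.numeric(x) * range + offset
}

#' Reduced cross-sectional problem
#'
#' Container for one (variable, exposure time, outcome interval) reduction of
#' a longitudinal study: covariates \code{W}, missingness indicator \code{C},
#' exposure \code{A} (defined exactly where \code{C = 1}) and binary outcome
#' \code{Y}, restricted to subjects at risk (alive) at the start of the
#' outcome interval.
#'
#' @param W numeric covariate matrix.
#' @param C 0/1 observedness indicator for the exposure.
#' @param A exposure vector; must be \code{NA} exactly where \code{C = 0}.
#'   Continuous exposures must lie in (0,1), binary in \code{{0,1}}.
#' @param Y outcome vector (binary for all estimation routines; a continuous
#'   Y is admitted for plug-in evaluation with user-supplied nuisances).
#' @param exposure_kind \code{"continuous"} or \code{"binary"}.
#' @param meta optional list of provenance fields (variable, exposure time
#'   \code{j}, outcome interval \code{j_prime}).
#' @return Object of class \code{"cross_section"}.
#' @export
cross_section <- function(W, C, A, Y,
                          exposure_kind = c("continuous", "binary"),
                          meta = list()) {
  exposure_kind <- match.arg(exposure_kind)
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (is.null(colnames(W))) colnames(W) <- paste0("W", seq_len(ncol(W)))
  n <- nrow(W)
  stopifnot(length(C) == n, length(A) == n, length(Y) == n,
            all(C %in% c(0, 1)))
  if (any(is.na(A) != (C == 0)))
    stop("A must be defined exactly where C = 1")
  a_obs <- A[C == 1]
  if (exposure_kind == "binary" && !is_binary01(a_obs))
    stop("binary exposure must take values in {0,1}")
  if (exposure_kind == "continuous" && any(a_obs <= 0 | a_obs >= 1))
    stop("continuous exposure must lie strictly inside (0,1)")
  if (any(is.na(Y))) stop("Y must be fully observed on the at-risk set")
  structure(list(W = W, C = as.numeric(C), A = as.numeric(A),
                 Y = as.numeric(Y), exposure_kind = exposure_kind,
                 meta = meta, n = n),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross-section: n = %d, %s exposure, %d adjustment covariates\n",
              x$n, x$exposure_kind, ncol(x$W)))
  if (length(x$meta))
    cat(sprintf("  variable %s, exposure time %s, outcome interval %s\n",
                x$meta$variable %||% "?", x$meta$j %||% "?",
                x$meta$j_prime %||% "?"))
  cat(sprintf("  observed exposure: %d/%d, outcome mean: %.3f\n",
              sum(x$C == 1), x$n, mean(x$Y)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a cross-sectional problem from longitudinal data
#'
#' Reduces the longitudinal study to the cross-section for the effect of
#' variable \code{k} measured at time \code{j} on death in interval
#' \code{j_prime >= j}.  Rows are restricted to subjects at risk (no death
#' before interval \code{j_prime}).  Under the Markov assumption the
#' adjustment set is \code{W = (L0, C[j-1,], L[j-1,])}: baseline covariates
#' plus the immediately preceding time point's covariates and missingness
#' flags; \code{history = "full"} uses the complete history instead.
#' Contemporaneous variables at time \code{j} are excluded (they are not
#' confounders under the causal model).  Missing past covariate values inside
#' \code{W} are filled with 0; their flags remain as covariates, so
#' missingness information is retained without imputation.
#'
#' @param data a [longitudinal_data()] object.
#' @param k variable index (1..K).
#' @param j exposure time index (1..J); \code{j = 1} is admission, giving
#'   \code{W = L0} only.
#' @param j_prime outcome interval index, \code{>= j}.
#' @param history \code{"markov"} (default) or \code{"full"}.
#' @return A [cross_section()] object.
#' @export
extract_cross_section <- function(data, k, j, j_prime,
                                  history = c("markov", "full")) {
  stopifnot(inherits(data, "longitudinal_data"))
  history <- match.arg(history)
  J <- data$J; K <- data$K
  if (!(k %in% seq_len(K))) stop("variable index k out of range")
  if (!(j %in% seq_len(J))) stop("exposure time j out of range")
  if (j_prime < j || j_prime > J) stop("need j <= j_prime <= J")

  # at risk at start of interval j_prime: no death in intervals < j_prime
  if (j_prime > 1L) {
    prior <- data$death[, seq_len(j_prime - 1L), drop = FALSE]
    at_risk <- rowSums(prior == 1, na.rm = TRUE) == 0
  } else {
    at_risk <- rep(TRUE, data$n)
  }
  if (!any(at_risk)) stop("empty cross-section: no subjects at risk")
  idx <- which(at_risk)

  past <- if (history == "markov" && j > 1L) j - 1L else seq_len(max(j - 1L, 0L))
  W <- data$baseline[idx, , drop = FALSE]
  if (j > 1L) {
    for (jj in past) {
      Lp <- data$covariates[idx, jj, , drop = TRUE]
      Cp <- data$miss_flags[idx, jj, , drop = TRUE]
      if (is.null(dim(Lp))) { Lp <- matrix(Lp, ncol = K); Cp <- matrix(Cp, ncol = K) }
      Lp[Cp == 0] <- 0  # fill; the flag column carries the information
      colnames(Lp) <- paste0(data$var_meta$name, "_t", jj)
      colnames(Cp) <- paste0(data$var_meta$name, "_obs_t", jj)
      W <- cbind(W, Cp, Lp)
    }
  }

  A <- data$covariates[idx, j, k]
  C <- data$miss_flags[idx, j, k]
  Y <- data$death[idx, j_prime]
  Y[is.na(Y)] <- 0
  kind <- data$var_meta$kind[k]
  # guard against boundary values for continuous exposures (0/1 after
  # rescaling): nudge into the open interval
  if (kind == "continuous") {
    A[!is.na(A)] <- pmin(pmax(A[!is.na(A)], 1e-4), 1 - 1e-4)
  }
  cross_section(W = W, C = C, A = A, Y = Y, exposure_kind = kind,
                meta = list(variable = data$var_meta$name[k], k = k, j = j,
                            j_prime = j_prime, n_at_risk = length(idx),
                            subject_id = data$subject_id[idx]))
}
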