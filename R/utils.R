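# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and integer tags.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed)
  for (t in tags) s <- (s * 131 + as.numeric(t) + 7919) %% 2147483629
  as.integer(s)
}

clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Minimise risk_fn(w) over the probability simplex in `k` dimensions.
# Softmax parameterisation + BFGS, equal-weight start (ties break toward
# equal weights); vertex safeguard guarantees the optimum is never worse
# than the best single candidate.
optimize_simplex_weights <- function(risk_fn, k) {
  if (k == 1L) return(1)
  softmax <- function(theta) {
    e <- exp(theta - max(theta))
    e / sum(e)
  }
  opt <- stats::optim(rep(0, k), function(theta) risk_fn(softmax(theta)),
                      method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  w <- softmax(opt$par)
  risk <- risk_fn(w)
  vertex_risk <- vapply(seq_len(k),
                        function(j) risk_fn(as.numeric(seq_len(k) == j)),
                        numeric(1))
  if (min(vertex_risk, na.rm = TRUE) < risk - 1e-10) {
    w <- as.numeric(seq_len(k) == which.min(vertex_risk))
  }
  w[w < 1e-8] <- 0
  w / sum(w)
}

# data.frame with standardised column names x1..xp used for all internal
# learner fits (keeps formulas safe for arbitrary input names).
as_learner_frame <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df
}

is_binary01 <- function(x) all(x %in% c(0, 1) | is.na(x))
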