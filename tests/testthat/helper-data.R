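# Shared helpers for the test suite.

# Small density candidate grids (keep tests fast).
dens_small <- data.frame(n_bins = 5L, placement = "equal_width",
                         stringsAsFactors = FALSE)
dens_two <- expand.grid(n_bins = c(5L, 10L), placement = "equal_width",
                        stringsAsFactors = FALSE)
# Full grid (both placements) for the replicated coverage study: the
# equal-frequency candidates are needed for calibrated inference near the
# sparse edges of the exposure support.
dens_full <- expand.grid(n_bins = c(5L, 10L, 20L),
                         placement = c("equal_width", "equal_frequency"),
                         stringsAsFactors = FALSE)

# Fast numerical controls for continuous-exposure estimation with a
# functional (true) density.
ctl_fast <- shiftvim_control(grid_cells = 50L, nodes_per_bin = 4L)

# A tiny hand-built longitudinal dataset: 5 subjects, 2 time points, 2
# variables; subject 3 dies in the first interval.
toy_longitudinal <- function() {
  n <- 5L; J <- 2L; K <- 2L
  baseline <- cbind(L0_sev = c(0.2, 0.4, 0.6, 0.8, 0.5),
                    L0_risk = c(0, 1, 0, 1, 1))
  covs <- array(NA_real_, c(n, J, K))
  flags <- array(0, c(n, J, K))
  covs[, 1, 1] <- c(0.1, 0.5, 0.9, 0.3, 0.7); flags[, 1, 1] <- 1
  covs[, 1, 2] <- c(0, 1, 1, 0, 1);            flags[, 1, 2] <- 1
  # at time 2 subject 3 is dead; subject 2's V1 is missing
  covs[c(1, 4, 5), 2, 1] <- c(0.2, 0.4, 0.6)
  flags[c(1, 4, 5), 2, 1] <- 1
  covs[c(1, 2, 4, 5), 2, 2] <- c(1, 0, 1, 0)
  flags[c(1, 2, 4, 5), 2, 2] <- 1
  death <- cbind(c(0, 0, 1, 0, 0), c(0, 1, NA, 0, 0))
  meta <- data.frame(name = c("V1", "V2"),
                     kind = c("continuous", "binary"),
                     role = "treatment", stringsAsFactors = FALSE)
  longitudinal_data(baseline, covs, flags, death, times = c(0, 1), meta)
}

# A fully observed binary-exposure cross-section with no confounding
# (W independent of A and Y | A).
unconfounded_binary_cs <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n), dimnames = list(NULL, "W1"))
  A <- rbinom(n, 1, 0.4)
  Y <- rbinom(n, 1, plogis(-0.5 + A))
  cross_section(W = W, C = rep(1, n), A = A, Y = Y, exposure_kind = "binary")
}
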