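test_that("rescale_unit_interval matches the direct formula and inverts", {
  expect_equal(as.numeric(rescale_unit_interval(c(2, 4, 6))), c(0, 0.5, 1))
  expect_equal(as.numeric(rescale_unit_interval(c(0, 1))), c(0, 1))
  expect_error(rescale_unit_interval(c(5, 5, 5)), "degenerate")

  x <- c(3.2, NA, -1.5, 7.8, 0)
  r <- rescale_unit_interval(x)
  expect_true(is.na(r[2]))
  expect_equal(unrescale_unit_interval(r), x, tolerance = 1e-12)
  expect_equal(min(r, na.rm = TRUE), 0)
  expect_equal(max(r, na.rm = TRUE), 1)
})

test_that("longitudinal_data enforces its invariants", {
  d <- toy_longitudinal()
  expect_s3_class(d, "longitudinal_data")
  # value present iff flag = 1
  expect_true(all(is.na(d$covariates[d$miss_flags == 0])))
  expect_true(all(!is.na(d$covariates[d$miss_flags == 1])))
  # death absorbing: subject 3 blanked after interval 1
  expect_true(is.na(d$death[3, 2]))
  expect_true(all(d$miss_flags[3, 2, ] == 0))

  # observed-value / flag mismatch rejected
  bad_flags <- d$miss_flags
  bad_flags[3, 2, 1] <- 1  # flagged observed but value NA
  expect_error(
    longitudinal_data(d$baseline, d$covariates, bad_flags, d$death, d$times,
                      d$var_meta),
    "observed")
})

test_that("extraction filters the at-risk set and j = 1 uses W = L0 only", {
  d <- toy_longitudinal()
  cs1 <- extract_cross_section(d, k = 1, j = 1, j_prime = 1)
  expect_equal(cs1$n, 5L)                       # everyone at risk in interval 1
  expect_equal(ncol(cs1$W), ncol(d$baseline))   # admission: baseline only
  cs2 <- extract_cross_section(d, k = 2, j = 2, j_prime = 2)
  expect_equal(cs2$n, 4L)                       # subject 3 died in interval 1
  expect_false(3 %in% cs2$meta$subject_id)
})

test_that("W assembly matches an independently built reference frame", {
  d <- generate_longitudinal(dgp_spec(n = 300, J = 3, K = 2, seed = 42))
  cs <- extract_cross_section(d, k = 1, j = 2, j_prime = 3)
  # reference: alive through intervals 1 and 2
  at_risk <- which(rowSums(d$death[, 1:2, drop = FALSE] == 1, na.rm = TRUE) == 0)
  expect_equal(cs$n, length(at_risk))
  L1 <- d$covariates[at_risk, 1, ]
  C1 <- d$miss_flags[at_risk, 1, ]
  L1[C1 == 0] <- 0
  ref <- cbind(d$baseline[at_risk, , drop = FALSE], C1, L1)
  expect_equal(unname(as.matrix(cs$W)), unname(ref))
  expect_equal(colnames(cs$W),
               c(colnames(d$baseline), "V1_obs_t1", "V2_obs_t1",
                 "V1_t1", "V2_t1"))
  # A/C/Y columns
  expect_equal(cs$C, as.numeric(d$miss_flags[at_risk, 2, 1]))
  expect_equal(cs$Y, as.numeric(d$death[at_risk, 3]))
})

test_that("rows removed by at-risk filtering equal cumulative prior deaths", {
  d <- generate_longitudinal(dgp_spec(n = 500, J = 3, K = 2, seed = 9))
  for (jp in 1:3) {
    cs <- extract_cross_section(d, k = 1, j = 1, j_prime = jp)
    prior_deaths <- if (jp == 1) 0 else
      sum(d$death[, seq_len(jp - 1), drop = FALSE] == 1, na.rm = TRUE)
    expect_equal(d$n - cs$n, prior_deaths)
  }
})

test_that("extraction is deterministic and validates indices", {
  d <- toy_longitudinal()
  expect_identical(extract_cross_section(d, 1, 1, 2),
                   extract_cross_section(d, 1, 1, 2))
  expect_error(extract_cross_section(d, 3, 1, 1), "out of range")
  expect_error(extract_cross_section(d, 1, 2, 1), "j <= j_prime")
})

test_that("long CSV round-trip preserves the study", {
  d <- generate_longitudinal(dgp_spec(n = 120, J = 2, K = 2, seed = 3))
  csv <- tempfile(fileext = ".csv"); meta <- tempfile(fileext = ".txt")
  write_longitudinal_csv(d, csv, meta)
  d2 <- read_longitudinal_csv(csv, meta, rescale = FALSE)
  expect_equal(d2$covariates, d$covariates, tolerance = 1e-8)
  expect_equal(d2$miss_flags, d$miss_flags)
  expect_equal(d2$death, d$death)
  expect_equal(d2$var_meta$kind, d$var_meta$kind)
  unlink(c(csv, meta))
})
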