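test_that("fc_from_timeseries yields a full product-moment matrix", {
  set.seed(1)
  ts379 <- matrix(rnorm(20 * 379), 20, 379)
  fc <- fc_from_timeseries(ts379)
  expect_equal(length(fc$values), 143641)   # 379^2 entries
  expect_equal(unname(diag(fc$values)), rep(1, 379))

  x <- rnorm(100)
  same <- cbind(a = x, b = x + 0, c = rnorm(100))
  expect_equal(fc_from_timeseries(same)$values["a", "b"], 1.0)
  anti <- cbind(a = x, b = -x)
  expect_equal(fc_from_timeseries(anti)$values["a", "b"], -1.0)

  const <- cbind(a = x, b = rep(2, 100))
  expect_error(fc_from_timeseries(const), "zero variance: b")
  expect_error(fc_from_timeseries(matrix(1:4, 1)), "2 time points")
})

test_that("geometric mean matches closed forms and fixed points", {
  M <- random_spd(4, seed = 2)
  expect_equal(geometric_mean_spd(list(M, M, M)), M, tolerance = 1e-9)
  expect_equal(geometric_mean_spd(list(M)), M)
  # commuting matrices: mean is (AB)^{1/2}
  A <- diag(c(1, 4)); B <- diag(c(4, 1))
  expect_equal(geometric_mean_spd(list(A, B)), diag(c(2, 2)),
               tolerance = 1e-10)
  # log-Euclidean agrees on commuting inputs
  expect_equal(geometric_mean_spd(list(A, B), type = "log_euclidean"),
               diag(c(2, 2)), tolerance = 1e-10)
  expect_error(geometric_mean_spd(list(diag(2), matrix(c(1, 2, 2, 1), 2))),
               "not positive definite")
})

test_that("tangent embedding round-trips and is zero at the reference", {
  ref <- random_spd(6, seed = 3)
  expect_equal(tangent_embed(ref, ref), matrix(0, 6, 6), tolerance = 1e-10)
  expect_equal(tangent_embed(matrix(exp(2)), matrix(1)), matrix(2.0))
  for (seed in 4:6) {
    C <- random_spd(6, seed = seed)
    T <- tangent_embed(C, ref)
    expect_identical(T, t(T))
    expect_lt(max(abs(tangent_invert(T, ref) - C)), 1e-8)
  }
  expect_error(tangent_embed(random_spd(3), random_spd(4)), "shape mismatch")
})

test_that("control tangent coefficients center at the geometric mean", {
  cfg <- sim_config(n_regions = 10, n_controls = 20, n_patients = 1, seed = 8)
  fcs <- lapply(simulate_controls(cfg), `[[`, "functional")
  ref <- fit_normative(fcs, atlas = cfg$atlas)
  # by construction of the Karcher mean, mean tangent coefficient ~ 0
  expect_lt(max(abs(ref$mu)), 0.05)
})

test_that("variance exclusion is exact, floored and stably tie-broken", {
  m <- variance_exclusion_mask(c(1, 2, 3, 4, 5, 6), 1/3)
  expect_identical(m, c(F, F, F, F, T, T))
  expect_identical(variance_exclusion_mask(1:6, 0), rep(FALSE, 6))
  expect_identical(variance_exclusion_mask(rep(1, 6), 1/3),
                   c(T, T, F, F, F, F))
  expect_error(variance_exclusion_mask(1:6, 1), "fraction")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:60, 1)
    v <- sample(rnorm(n), n)     # may include ties after rounding
    f <- runif(1, 0, 0.9)
    mask <- variance_exclusion_mask(v, f)
    expect_equal(sum(mask), floor(f * n))
    if (any(mask) && any(!mask))
      expect_gte(min(v[mask]), max(v[!mask]) - 1e-12)
  }
})

test_that("fit_normative estimates per-edge moments and masks top variance", {
  # toy 4-region cohort, 6 edges: exclusion keeps exactly floor(6/3) = 2 out
  cohort <- small_structural_cohort(n_regions = 4, n_subjects = 8, seed = 2)
  ref <- fit_normative(cohort, exclusion_fraction = 1/3)
  expect_length(ref$mu, 6)
  expect_equal(sum(ref$excluded), 2)
  expect_gte(min(ref$variance[ref$excluded]), max(ref$variance[!ref$excluded]))
  # brute-force moments on the log1p representation
  X <- t(sapply(cohort, function(s) log1p(s$values[upper.tri(s$values)])))
  expect_equal(ref$mu, colMeans(X))
  expect_equal(ref$sigma, apply(X, 2, sd))

  # Monte-Carlo: Gaussian edge with known moments recovered within 3 SE
  set.seed(10)
  n_sub <- 1000
  vals <- rnorm(n_sub, mean = 8, sd = 2)   # the edge's log1p values
  ms <- lapply(seq_len(n_sub), function(s) {
    m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- expm1(vals[s])
    m[1, 3] <- m[3, 1] <- s; m[2, 3] <- m[3, 2] <- 2 * s
    conn_matrix(m, "structural", paste0("s", s))
  })
  ref2 <- fit_normative(ms, exclusion_fraction = 0)
  expect_lt(abs(ref2$mu[1] - 8), 3 * 2 / sqrt(n_sub))
  expect_lt(abs(ref2$sigma[1] - 2), 3 * 2 / sqrt(2 * n_sub))
})

test_that("constant edges are degenerate, never anomalous", {
  ms <- lapply(1:5, function(s) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- 7            # identical across subjects
    m[1, 3] <- m[3, 1] <- s
    m[2, 3] <- m[3, 2] <- s^2
    conn_matrix(m, "structural", paste0("s", s))
  })
  ref <- fit_normative(ms, exclusion_fraction = 0)
  expect_true(ref$degenerate[1])
  probe <- conn_matrix(matrix(c(0, 999, 0, 999, 0, 0, 0, 0, 0), 3),
                       "structural", "probe")
  am <- detect_anomalies(probe, ref)
  expect_equal(am$status[1], "degenerate")
  expect_true(is.na(am$zscore[1]))
})

test_that("fit_normative is invariant to subject order and validates input", {
  cohort <- small_structural_cohort(n_regions = 8, n_subjects = 6, seed = 3)
  r1 <- fit_normative(cohort)
  r2 <- fit_normative(rev(cohort))
  expect_equal(r1$mu, r2$mu)
  expect_equal(r1$sigma, r2$sigma)
  expect_identical(r1$excluded, r2$excluded)
  expect_error(fit_normative(cohort[1:2]), "at least 3")
  mixed <- c(cohort[1:2], list(conn_matrix(diag(8), "functional", "f")))
  expect_error(fit_normative(mixed), "mixes modalities")
})

test_that("log1p structural representation is monotone in the count", {
  cohort <- small_structural_cohort(n_regions = 5, n_subjects = 4, seed = 4)
  base <- cohort[[1]]$values
  for (delta in c(1, 10, 1000)) {
    bumped <- base
    bumped[1, 2] <- bumped[2, 1] <- base[1, 2] + delta
    v0 <- normconn:::representation_values(base, "log1p_count")
    v1 <- normconn:::representation_values(bumped, "log1p_count")
    expect_gt(v1[1], v0[1])
    expect_equal(v1[-1], v0[-1])
  }
})

test_that("excluded and retained edges always partition the edge set", {
  for (n in c(4, 7, 12)) {
    cohort <- small_structural_cohort(n_regions = n, n_subjects = 5, seed = n)
    ref <- fit_normative(cohort, exclusion_fraction = 1/3)
    ne <- n * (n - 1) / 2
    expect_equal(sum(ref$excluded) + sum(!ref$excluded), ne)
    expect_equal(sum(ref$excluded), floor(ne / 3))
  }
})
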