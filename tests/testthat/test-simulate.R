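test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_regions = 15, n_controls = 5, n_patients = 3, seed = 7)
  c1 <- simulate_controls(cfg)
  c2 <- simulate_controls(cfg)
  expect_identical(c1, c2)
  p1 <- simulate_patients(cfg)
  p2 <- simulate_patients(cfg)
  expect_identical(p1, p2)
  # a different seed changes the draw
  c3 <- simulate_controls(sim_config(n_regions = 15, n_controls = 5,
                                     n_patients = 3, seed = 8))
  expect_false(identical(c1[[1]]$structural$values,
                         c3[[1]]$structural$values))
})

test_that("cohort sizes and matrix shapes honor the configuration", {
  cfg <- sim_config(n_regions = 20, n_controls = 41, n_patients = 21, seed = 2)
  ctrl <- simulate_controls(cfg)
  expect_length(ctrl, 41)
  pats <- simulate_patients(cfg)
  expect_length(pats$subjects, 21)
  expect_equal(dim(ctrl[[1]]$structural$values), c(20, 20))
  expect_equal(dim(ctrl[[1]]$functional$values), c(20, 20))
})

test_that("structural matrices are integer counts, symmetric, zero diagonal", {
  cfg <- sim_config(n_regions = 18, n_controls = 6, n_patients = 2, seed = 4)
  for (s in simulate_controls(cfg)) {
    m <- s$structural$values
    expect_identical(m, t(m))
    expect_equal(diag(m), setNames(rep(0, 18), rownames(m)))
    expect_true(all(m >= 0))
    expect_equal(m, round(m))
  }
})

test_that("functional matrices are valid correlation matrices (PSD)", {
  cfg <- sim_config(n_regions = 25, n_controls = 8, n_patients = 2, seed = 5)
  for (s in simulate_controls(cfg)) {
    m <- s$functional$values
    expect_identical(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 25))
    expect_true(max(abs(m)) <= 1 + 1e-12)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("identity effects leave the patient draw untouched", {
  cfg <- sim_config(n_regions = 12, n_controls = 4, n_patients = 3, seed = 11)
  plain <- simulate_patients(cfg)
  spec <- anomaly_spec(rbind(c("L_r001", "R_r002"), c("L_r003", "R_r004")),
                       sc_multiplier = 1, fc_shift_sigmas = 0)
  planted <- simulate_patients(cfg, spec)
  for (s in seq_along(plain$subjects)) {
    expect_equal(planted$subjects[[s]]$structural$values,
                 plain$subjects[[s]]$structural$values)
    expect_equal(planted$subjects[[s]]$functional$values,
                 plain$subjects[[s]]$functional$values,
                 tolerance = 1e-12)
  }
  # ground truth still lists every planted (subject, edge, modality)
  expect_equal(nrow(planted$ground_truth), 3 * 2 * 2)
})

test_that("patients share the control code path up to effect injection", {
  cfg <- sim_config(n_regions = 10, n_controls = 5, n_patients = 5, seed = 9)
  pop <- normconn:::sim_population(cfg)
  ctrl_stream <- normconn:::sim_subjects(cfg, pop, 5, "x", cfg$seed + 2L)
  pats <- simulate_patients(cfg)
  for (s in 1:5) {
    expect_equal(pats$subjects[[s]]$structural$values,
                 ctrl_stream[[s]]$structural$values)
    expect_equal(pats$subjects[[s]]$functional$values,
                 ctrl_stream[[s]]$functional$values)
  }
})

test_that("planted effects modify exactly the listed pairs", {
  cfg <- sim_config(n_regions = 12, n_controls = 4, n_patients = 3, seed = 6)
  edges <- rbind(c("L_r001", "R_r006"), c("L_r005", "L_r007"))
  spec <- anomaly_spec(edges, sc_multiplier = 0.3, fc_shift_sigmas = 4,
                       carriers = c("patient01", "patient03"))
  plain <- simulate_patients(cfg)
  planted <- simulate_patients(cfg, spec)
  expect_equal(nrow(planted$ground_truth), 2 * 2 * 2)
  expect_setequal(unique(planted$ground_truth$subject),
                  c("patient01", "patient03"))
  a <- normconn:::atlas_lookup(cfg$atlas, edges[, 1])
  b <- normconn:::atlas_lookup(cfg$atlas, edges[, 2])
  for (s in seq_along(plain$subjects)) {
    diff_sc <- plain$subjects[[s]]$structural$values !=
      planted$subjects[[s]]$structural$values
    carried <- plain$subjects[[s]]$id %in% c("patient01", "patient03")
    if (!carried) {
      expect_false(any(diff_sc))
    } else {
      # only planted cells (and their transposes) may differ
      allowed <- matrix(FALSE, 12, 12)
      allowed[cbind(c(a, b), c(b, a))] <- TRUE
      expect_true(all(!diff_sc | allowed))
      # the planted count is the rounded multiple of the original
      orig <- plain$subjects[[s]]$structural$values[a[1], b[1]]
      expect_equal(planted$subjects[[s]]$structural$values[a[1], b[1]],
                   round(orig * 0.3))
    }
  }
  expect_error(simulate_patients(cfg, anomaly_spec(rbind(c("L_r001", "nope")))),
               "unknown region")
})

test_that("emitted time series converge to the target correlation", {
  cfg <- sim_config(n_regions = 5, n_controls = 3, n_patients = 1, seed = 3,
                    timepoints = 50000)
  target <- random_spd(5, seed = 42)
  ts <- emit_timeseries(cfg, target, seed = 99)
  expect_equal(dim(ts), c(50000, 5))
  expect_lt(max(abs(cor(ts) - cov2cor(target))), 0.02)
  expect_identical(ts, emit_timeseries(cfg, target, seed = 99))
  expect_error(sim_config(n_regions = 5, n_controls = 3, timepoints = 1),
               "timepoints")
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(sim_config(n_regions = 10, n_controls = 2), "n_controls")
  expect_error(sim_config(n_regions = 10, sc_log_sd = 0), "sc_log_sd")
  expect_error(sim_config(n_regions = 10, fc_sample_df = 5), "fc_sample_df")
  expect_error(anomaly_spec(rbind(c("A", "A"))), "self-edges")
  expect_error(anomaly_spec(rbind(c("A", "B"), c("B", "A"))), "distinct")
  expect_error(anomaly_spec(rbind(c("A", "B")), sc_multiplier = 0),
               "sc_multiplier")
})
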