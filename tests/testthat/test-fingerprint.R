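test_that("burden arithmetic reproduces hand-computed rows", {
  # a region with 634 flagged incidences over 218 retained edges and
  # 21 subjects has 4,578 potential anomalies and a 13.85% burden
  row <- burden_arithmetic(634, 218, 21)
  expect_equal(row$total_potential, 4578)
  expect_equal(row$percentage, 13.85)
  expect_equal(burden_arithmetic(0, 100, 21)$percentage, 0)
  expect_equal(burden_arithmetic(5, 0, 21)$percentage, 0)
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.135, 2), 0.14)   # base round() would give 0.14/0.13 mix
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(13.849, 2), 13.85)
})

test_that("burden and frequency tables match brute-force enumeration", {
  for (draw in 1:200) {
    set.seed(draw)
    n <- sample(3:6, 1)
    n_sub <- sample(1:4, 1)
    fix <- random_status_cohort(n, n_sub, seed = draw + 1000)
    for (direction in c("low", "both")) {
      flags <- if (direction == "low") "anomaly_low"
               else c("anomaly_low", "anomaly_high")
      got <- burden_table(fix$anomalies, synthetic_atlas(n), fix$reference,
                          direction = direction)
      want <- brute_burden(fix$statuses, fix$reference, flags)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("edge frequency counts, annotation and ordering are correct", {
  a <- default_atlas()
  n <- n_regions(a)
  ne <- n * (n - 1) / 2
  pairs <- normconn:::edge_pairs(n)
  key <- function(r1, r2) which(
    (a$index[r1] == pairs[, 1] & a$index[r2] == pairs[, 2]) |
      (a$index[r2] == pairs[, 1] & a$index[r1] == pairs[, 2]))
  # plant three edges at frequencies 3, 1, 2 over 3 subjects
  e1 <- key("R_caudate", "R_OFC")   # flagged in all 3
  e2 <- key("R_2", "L_IFJa")        # flagged in 1
  e3 <- key("R_p24", "R_24dd")      # flagged in 2
  statuses <- lapply(1:3, function(s) {
    st <- rep("normal", ne)
    st[e1] <- "anomaly_low"
    if (s == 1) st[e2] <- "anomaly_low"
    if (s <= 2) st[e3] <- "anomaly_low"
    st
  })
  ams <- lapply(seq_along(statuses), function(s) {
    am <- make_anomaly(statuses[[s]], n, sprintf("p%d", s))
    am$region_names <- a$regions$name
    am
  })
  tab <- edge_frequency_table(ams, a, direction = "low")
  expect_equal(tab$n_patients, c(3, 2, 1))        # sorted descending
  expect_equal(tab$region_a[1], "R_OFC")          # canonical order i < j
  expect_equal(tab$region_b[1], "R_caudate")
  expect_equal(tab$affiliation_a[1], "Orbitofrontal")
  expect_equal(tab$affiliation_b[1], "Basal ganglia")
  expect_equal(tab$hemisphere_relation[1], "right")
  expect_equal(tab$relationship[1], "corticobasal")
  expect_equal(tab$relationship[3], "interhemispheric")
  expect_equal(tab$hemisphere_relation[3], "bilateral")
})

test_that("frequency sort is verified against brute force on random toys", {
  for (draw in 1:50) {
    n <- 5
    fix <- random_status_cohort(n, 4, seed = draw + 2000)
    got <- edge_frequency_table(fix$anomalies, synthetic_atlas(n),
                                direction = "both")
    want <- brute_frequency(fix$statuses, fix$reference,
                            c("anomaly_low", "anomaly_high"))
    expect_setequal(paste(got$region_a, got$region_b, got$n_patients),
                    paste(want$region_a, want$region_b, want$n_patients))
    expect_true(all(diff(got$n_patients) <= 0))
    expect_true(all(got$n_patients >= 1))
  }
})

test_that("double-counting identities hold on simulated detections", {
  cfg <- sim_config(n_regions = 20, n_controls = 12, n_patients = 5, seed = 17)
  ctrl <- lapply(simulate_controls(cfg), `[[`, "structural")
  ref <- fit_normative(ctrl)
  ams <- cohort_detect(lapply(simulate_patients(cfg)$subjects,
                              `[[`, "structural"), ref)
  tab <- burden_table(ams, cfg$atlas, ref, direction = "both")
  flagged_pairs <- sum(sapply(ams, function(am)
    sum(am$status %in% c("anomaly_low", "anomaly_high"))))
  expect_equal(sum(tab$n_anomalies), 2 * flagged_pairs)
  retained <- sum(!ref$excluded & !ref$degenerate)
  expect_equal(sum(tab$n_low_variance), 2 * retained)
  expect_true(all(tab$n_low_variance <= n_regions(cfg$atlas) - 1))
  expect_true(all(tab$percentage >= 0 & tab$percentage <= 100))
  expect_true(all(tab$n_subjects_with_anomaly <= length(ams)))
})

test_that("a cohort with no anomalies yields an all-zero burden table", {
  n <- 5
  ne <- n * (n - 1) / 2
  statuses <- lapply(1:2, function(s) rep("normal", ne))
  ams <- lapply(1:2, function(s) make_anomaly(statuses[[s]], n,
                                              sprintf("s%d", s)))
  ref <- make_matching_reference(statuses, n)
  tab <- burden_table(ams, synthetic_atlas(n), ref)
  expect_true(all(tab$n_anomalies == 0))
  expect_true(all(tab$percentage == 0))
  expect_equal(nrow(edge_frequency_table(ams, synthetic_atlas(n))), 0)
})

test_that("network submatrices restrict to members and localize anomalies", {
  a <- mixed_atlas()          # DMN = {L_ctx1, R_ctx1}, CEN = {L_ctx2, R_ctx2}
  n <- n_regions(a)
  ne <- n * (n - 1) / 2
  pairs <- normconn:::edge_pairs(n)
  st <- rep("normal", ne)
  dmn_edge <- which(pairs[, 1] == 1 & pairs[, 2] == 3)  # L_ctx1 - R_ctx1
  st[dmn_edge] <- "anomaly_low"
  am <- make_anomaly(st, n)
  am$region_names <- a$regions$name
  sm <- network_submatrix(am, a, "DMN")
  expect_equal(dim(sm), c(2, 2))
  expect_equal(sm["L_ctx1", "R_ctx1"], "anomaly_low")
  expect_false(any(network_submatrix(am, a, "CEN") == "anomaly_low"))
  # all-excluded cohort renders entirely as the excluded state
  am2 <- make_anomaly(rep("excluded", ne), n)
  am2$region_names <- a$regions$name
  expect_true(all(network_submatrix(am2, a, "DMN") == "excluded"))
  # singleton networks are rejected
  one <- synthetic_atlas(6)
  am3 <- make_anomaly(rep("normal", 15), 6)
  am3$region_names <- one$regions$name
  expect_error(network_submatrix(am3, one, "nope"), "unknown network")
  expect_error(network_submatrix(am3, one, "Sensorimotor"),
               "fewer than 2 members")
})
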