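# Shared fixture builders. Everything is generated in code at test time.

# A 4-region toy atlas written to a temp file, for the file-parsing path.
write_toy_atlas <- function(path = tempfile(fileext = ".tsv")) {
  tab <- data.frame(
    name = c("L_a", "L_b", "R_a", "R_b"),
    hemisphere = c("left", "left", "right", "right"),
    kind = "cortical", subcortical_class = "none",
    lobe = c("Frontal", "Parietal", "Frontal", "Parietal"),
    network = c("DMN", "DMN", "CEN", "CEN"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_atlas <- function() load_atlas(write_toy_atlas())

# A mixed toy atlas with subcortical structures and a midline region.
mixed_atlas <- function() {
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(
    name = c("L_ctx1", "L_ctx2", "R_ctx1", "R_ctx2",
             "L_caud", "R_thal", "L_hipp", "R_amyg", "Mid_bs"),
    hemisphere = c("left", "left", "right", "right",
                   "left", "right", "left", "right", "midline"),
    kind = c(rep("cortical", 4), rep("subcortical", 5)),
    subcortical_class = c(rep("none", 4), "basal_ganglia", "thalamus",
                          "hippocampus", "amygdala", "brainstem"),
    lobe = c("Frontal", "Parietal", "Frontal", "Parietal", rep("Sub", 5)),
    network = c("DMN", "CEN", "DMN", "CEN", rep("Subcortical", 5)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_atlas(path)
}

random_spd <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n + diag(n)
}

# A structural control cohort over a synthetic atlas.
small_structural_cohort <- function(n_regions = 12, n_subjects = 8, seed = 1) {
  cfg <- sim_config(n_regions = n_regions, n_controls = max(n_subjects, 3),
                    n_patients = 1, seed = seed)
  lapply(simulate_controls(cfg)[seq_len(n_subjects)], `[[`, "structural")
}

# Build a normative reference directly with injected per-edge moments
# (raw-count representation), for analytic calibration tests.
make_raw_reference <- function(mu, sigma, n, k_sigma = 3,
                               excluded = rep(FALSE, length(mu)),
                               degenerate = sigma == 0,
                               region_names = sprintf("region_%03d",
                                                      seq_len(n))) {
  pairs <- normconn:::edge_pairs(n)
  ne <- length(mu)
  stopifnot(ne == n * (n - 1) / 2)
  variance <- sigma^2
  rank <- integer(ne)
  rank[order(-variance, seq_len(ne))] <- seq_len(ne)
  structure(list(
    modality = "structural", representation = "raw_count",
    reference_matrix = NULL, mu = mu, sigma = sigma, variance = variance,
    variance_rank = rank, excluded = excluded, degenerate = degenerate,
    n_controls = 99L, n_regions = n,
    region_names = region_names,
    edge_i = pairs[, 1], edge_j = pairs[, 2],
    exclusion_fraction = mean(excluded), k_sigma = k_sigma,
    shrinkage = 1e-3, mean_type = "karcher"),
    class = "normative_reference")
}

# Build an anomaly_matrix directly from a status vector (for aggregation
# oracles that do not involve detection).
make_anomaly <- function(status, n, subject_id = "s1",
                         modality = "structural",
                         region_names = synthetic_atlas(n)$regions$name) {
  pairs <- normconn:::edge_pairs(n)
  z <- ifelse(status == "anomaly_low", -4,
              ifelse(status == "anomaly_high", 4,
                     ifelse(status == "normal", 0, NA_real_)))
  structure(list(subject_id = subject_id, modality = modality,
                 status = status, zscore = z, k_sigma = 3,
                 n_regions = n,
                 region_names = region_names,
                 edge_i = pairs[, 1], edge_j = pairs[, 2]),
            class = "anomaly_matrix")
}

# Matching reference for make_anomaly cohorts: excluded/degenerate edges are
# those statuses shared across all subjects.
make_matching_reference <- function(statuses, n) {
  excluded <- statuses[[1]] == "excluded"
  degenerate <- statuses[[1]] == "degenerate"
  mu <- rep(0, n * (n - 1) / 2)
  sigma <- ifelse(degenerate, 0, 1)
  make_raw_reference(mu, sigma, n, excluded = excluded,
                     degenerate = degenerate,
                     region_names = synthetic_atlas(n)$regions$name)
}

# Random status cohorts over a toy problem: shared excluded/degenerate mask,
# independent anomaly placement per subject.
random_status_cohort <- function(n_regions, n_subjects, seed) {
  set.seed(seed)
  ne <- n_regions * (n_regions - 1) / 2
  base <- sample(c("edge", "excluded", "degenerate"), ne, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  statuses <- lapply(seq_len(n_subjects), function(s) {
    st <- ifelse(base == "edge",
                 sample(c("normal", "anomaly_low", "anomaly_high"), ne,
                        replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                 base)
    st
  })
  anomalies <- lapply(seq_len(n_subjects), function(s)
    make_anomaly(statuses[[s]], n_regions, sprintf("s%02d", s)))
  list(anomalies = anomalies,
       reference = make_matching_reference(statuses, n_regions),
       statuses = statuses)
}

# Brute-force burden oracle: exhaustive loop over (subject, edge, region).
brute_burden <- function(statuses, reference, flag_values) {
  n <- reference$n_regions
  names <- reference$region_names
  n_sub <- length(statuses)
  pairs <- cbind(reference$edge_i, reference$edge_j)
  rows <- lapply(seq_len(n), function(r) {
    n_anom <- 0L; subj <- logical(n_sub); n_lv <- 0L
    for (e in seq_len(nrow(pairs))) {
      incident <- pairs[e, 1] == r || pairs[e, 2] == r
      if (!incident) next
      if (!reference$excluded[e] && !reference$degenerate[e])
        n_lv <- n_lv + 1L
      for (s in seq_len(n_sub)) {
        if (statuses[[s]][e] %in% flag_values) {
          n_anom <- n_anom + 1L
          subj[s] <- TRUE
        }
      }
    }
    data.frame(region = names[r], n_anomalies = n_anom,
               n_subjects_with_anomaly = sum(subj), n_low_variance = n_lv,
               total_potential = n_lv * n_sub,
               percentage = if (n_lv > 0) 100 * n_anom / (n_lv * n_sub) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$percentage, -out$n_anomalies, out$region), , drop = FALSE]
}

# Brute-force edge-frequency oracle.
brute_frequency <- function(statuses, reference, flag_values) {
  counts <- Reduce(`+`, lapply(statuses, function(st) st %in% flag_values))
  keep <- which(counts > 0)
  data.frame(n_patients = counts[keep],
             region_a = reference$region_names[reference$edge_i[keep]],
             region_b = reference$region_names[reference$edge_j[keep]],
             stringsAsFactors = FALSE)
}
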