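#' Read a connectivity matrix from delimited text
#'
#' Expects a square numeric table whose first row and first column carry
#' region names. Names must match the atlas exactly as a set; a permuted file
#' is reordered to atlas order. Asymmetry up to `1e-6` is symmetrized by
#' averaging; beyond that it is an error. Functional diagonals are forced
#' to 1.
#'
#' @param path file path.
#' @param atlas a `conn_atlas`.
#' @param modality `"structural"` or `"functional"`.
#' @param subject_id subject identifier (default: file name without
#'   extension).
#' @param sep field separator (default tab).
#' @return a `conn_matrix`.
#' @export
read_connectivity_matrix <- function(path, atlas,
                                     modality = c("structural", "functional"),
                                     subject_id = NULL, sep = "\t") {
  modality <- match.arg(modality)
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  tab <- utils::read.delim(path, sep = sep, check.names = FALSE,
                           row.names = 1, quote = "")
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric cell(s) in ", path)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  unknown <- setdiff(rownames(m), atlas$regions$name)
  if (length(unknown) > 0)
    stop("unknown region name(s) in ", path, ": ",
         paste(utils::head(unknown, 5), collapse = ", "))
  missing <- setdiff(atlas$regions$name, rownames(m))
  if (length(missing) > 0)
    stop("region(s) missing from ", path, ": ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!identical(rownames(m), colnames(m)))
    stop("row and column names disagree in ", path)
  m <- m[atlas$regions$name, atlas$regions$name]
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop("matrix in ", path, " is asymmetric beyond tolerance (", format(asym), ")")
  m <- (m + t(m)) / 2
  if (modality == "functional") diag(m) <- 1
  conn_matrix(m, modality, subject_id = subject_id, atlas = atlas)
}

#' Write a connectivity matrix as delimited text
#'
#' @param cm a `conn_matrix`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(cm, path, sep = "\t") {
  stopifnot(inherits(cm, "conn_matrix"))
  df <- data.frame(region = rownames(cm$values), cm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a normative reference to plain text
#'
#' Writes up to three files into `dir`: the per-edge moment table
#' (`<modality>_edges.tsv`), a JSON sidecar with the fitting parameters and an
#' atlas checksum (`<modality>_reference.json`), and — for functional
#' references — the SPD reference matrix (`<modality>_reference_matrix.tsv`).
#'
#' @param reference a `normative_reference`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_normative_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "normative_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- reference$modality
  edge_path <- file.path(dir, paste0(base, "_edges.tsv"))
  utils::write.table(coef(reference), edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- edge_path
  if (!is.null(reference$reference_matrix)) {
    mat_path <- file.path(dir, paste0(base, "_reference_matrix.tsv"))
    m <- reference$reference_matrix
    dimnames(m) <- list(reference$region_names, reference$region_names)
    utils::write.table(data.frame(region = rownames(m), m, check.names = FALSE),
                       mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, mat_path)
  }
  json_path <- file.path(dir, paste0(base, "_reference.json"))
  jsonlite::write_json(list(
    modality = reference$modality, representation = reference$representation,
    exclusion_fraction = reference$exclusion_fraction,
    k_sigma = reference$k_sigma, n_controls = reference$n_controls,
    n_regions = reference$n_regions, shrinkage = reference$shrinkage,
    mean_type = reference$mean_type,
    atlas_checksum = names_checksum(reference$region_names)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, json_path))
}

# md5 of the newline-joined region names, via a temp file (tools::md5sum).
names_checksum <- function(names) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(names, tf)
  unname(tools::md5sum(tf))
}

#' Write anomaly matrices as a long-format table
#'
#' One row per (subject, edge): `subject`, `region_a`, `region_b`,
#' `modality`, `zscore`, `status`.
#'
#' @param anomalies list of `anomaly_matrix` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anomalies <- function(anomalies, path) {
  check_anomaly_list(anomalies)
  long <- do.call(rbind, lapply(anomalies, as.data.frame))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' @param sim a [sim_config()] describing the cohorts to simulate.
#' @param anomalies an [anomaly_spec()] of planted patient effects, or `NULL`.
#' @param exclusion_fraction fraction of highest-variance edges excluded
#'   (default 1/3).
#' @param k_sigma detection threshold (default 3).
#' @param structural_direction burden/frequency direction for structural
#'   anomalies (default `"low"`: fiber loss).
#' @param functional_direction same for functional (default `"both"`).
#' @param modalities which modalities to run (default both).
#' @param submatrix_networks network labels to write status submatrices for
#'   (default `"DMN"` when present in the atlas).
#' @param output_dir output directory.
#' @param seed run seed; overrides `sim$seed` so one seed controls the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, anomalies = NULL, exclusion_fraction = 1/3,
                            k_sigma = 3, structural_direction = "low",
                            functional_direction = "both",
                            modalities = c("structural", "functional"),
                            submatrix_networks = "DMN",
                            output_dir = tempfile("normconn_run_"),
                            seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"))
  if (exclusion_fraction < 0 || exclusion_fraction >= 1)
    stop("exclusion_fraction must be in [0, 1)")
  if (k_sigma <= 0) stop("k_sigma must be positive")
  modalities <- match.arg(modalities, several.ok = TRUE)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, anomalies = anomalies,
                 exclusion_fraction = exclusion_fraction, k_sigma = k_sigma,
                 structural_direction = structural_direction,
                 functional_direction = functional_direction,
                 modalities = modalities,
                 submatrix_networks = submatrix_networks,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full anomaly-fingerprinting pipeline
#'
#' Simulates (or accepts) control and patient cohorts, fits the normative
#' reference per modality, scores every patient, and writes the normative
#' tables, long-format anomaly files, burden and edge-frequency tables,
#' network submatrices and a JSON run manifest with file checksums. The same
#' configuration and seed reproduce every output byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param controls,patients optional pre-built cohorts (as returned by
#'   [simulate_controls()] / [simulate_patients()]); simulated when `NULL`.
#' @param verbose log per-stage edge counts (default `TRUE`).
#' @return the output bundle, invisibly: a list with per-modality references,
#'   anomaly lists, burden and frequency tables, the ground-truth table and
#'   the manifest.
#' @export
run_pipeline <- function(config, controls = NULL, patients = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- config$sim$atlas
  say <- function(...) if (verbose) message(...)

  if (is.null(controls)) controls <- simulate_controls(config$sim)
  if (is.null(patients)) patients <- simulate_patients(config$sim,
                                                       config$anomalies)
  gt <- patients$ground_truth
  pat_subjects <- patients$subjects
  say("cohorts: ", length(controls), " controls, ", length(pat_subjects),
      " patients, ", n_regions(atlas), " regions")

  bundle <- list(config = config, ground_truth = gt)
  files <- character()
  if (nrow(gt) > 0) {
    gt_path <- file.path(config$output_dir, "ground_truth.tsv")
    utils::write.table(gt, gt_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, gt_path)
  }

  for (modality in config$modalities) {
    stage <- paste0("fit_normative[", modality, "]")
    ctrl <- lapply(controls, `[[`, modality)
    ref <- tryCatch(
      fit_normative(ctrl, exclusion_fraction = config$exclusion_fraction,
                    k_sigma = config$k_sigma, atlas = atlas),
      error = function(e) stop(stage, ": ", conditionMessage(e), call. = FALSE))
    say(stage, ": ", length(ref$mu), " edges, ", sum(ref$excluded),
        " excluded, ", sum(ref$degenerate & !ref$excluded), " degenerate")

    pat <- lapply(pat_subjects, `[[`, modality)
    ams <- cohort_detect(pat, ref, verbose = verbose)
    n_flag <- sum(vapply(ams, function(a)
      sum(a$status %in% c("anomaly_low", "anomaly_high")), 0L))
    say("detect[", modality, "]: ", n_flag, " flagged (subject, edge) pairs")

    direction <- if (modality == "structural") config$structural_direction
                 else config$functional_direction
    burden <- burden_table(ams, atlas, ref, direction = direction)
    freq <- edge_frequency_table(ams, atlas, direction = direction)

    files <- c(files, write_normative_reference(ref, config$output_dir))
    anom_path <- file.path(config$output_dir,
                           paste0(modality, "_anomalies.tsv"))
    write_anomalies(ams, anom_path)
    burden_out <- burden
    burden_out$percentage <- round_half_up(burden_out$percentage, 2)
    burden_path <- file.path(config$output_dir,
                             paste0(modality, "_burden.tsv"))
    utils::write.table(burden_out, burden_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    freq_path <- file.path(config$output_dir,
                           paste0(modality, "_frequency.tsv"))
    utils::write.table(freq, freq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, anom_path, burden_path, freq_path)

    nets <- intersect(config$submatrix_networks,
                      unique(atlas$regions$network))
    for (net in nets) {
      if (length(network_members(atlas, net)) < 2) next
      sm <- network_submatrix(ams[[1]], atlas, net)
      sm_path <- file.path(config$output_dir,
                           paste0(modality, "_submatrix_",
                                  gsub("[^A-Za-z0-9]", "_", net), "_",
                                  ams[[1]]$subject_id, ".tsv"))
      utils::write.table(data.frame(region = rownames(sm), sm,
                                    check.names = FALSE),
                         sm_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, sm_path)
    }

    bundle[[modality]] <- list(reference = ref, anomalies = ams,
                               burden = burden, frequency = freq)
  }

  manifest <- list(
    package = "normconn",
    version = as.character(utils::packageVersion("normconn")),
    seed = config$seed,
    n_regions = config$sim$n_regions,
    n_controls = config$sim$n_controls,
    n_patients = config$sim$n_patients,
    exclusion_fraction = config$exclusion_fraction,
    k_sigma = config$k_sigma,
    modalities = config$modalities,
    atlas_checksum = names_checksum(atlas$regions$name),
    files = as.list(tools::md5sum(sort(files))))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  bundle$files <- c(files, manifest_path)
  invisible(bundle)
}

#' Render a plain-text summary report of a pipeline bundle
#'
#' Prints the top rows of each modality's burden table (with the canonical
#' column headers) and of the edge-frequency table.
#'
#' @param bundle a [run_pipeline()] result.
#' @param top rows to show per table (default 10; larger than the table shows
#'   everything).
#' @return the report lines, invisibly; printed as a side effect.
#' @export
write_report <- function(bundle, top = 10) {
  headers <- c("Parcellation", "No. of anomalies",
               "No. of subjects with at least one anomaly",
               "No. of low variance connections",
               "Total potential anomalies", "Percentage of total %")
  lines <- character()
  push <- function(...) lines <<- c(lines, paste0(...))
  for (modality in bundle$config$modalities) {
    res <- bundle[[modality]]
    if (is.null(res)) next
    push("== ", toupper(substring(modality, 1, 1)), substring(modality, 2),
         " anomaly burden ==")
    push(paste(headers, collapse = "\t"))
    b <- utils::head(res$burden, top)
    for (r in seq_len(nrow(b)))
      push(paste(b$region[r], b$n_anomalies[r], b$n_subjects_with_anomaly[r],
                 b$n_low_variance[r], b$total_potential[r],
                 sprintf("%.2f", round_half_up(b$percentage[r], 2)),
                 sep = "\t"))
    push("")
    push("== ", toupper(substring(modality, 1, 1)), substring(modality, 2),
         " anomaly frequency ==")
    push(paste(c("Patients", "Affiliation 1", "Parcellation 1",
                 "Parcellation 2", "Affiliation 2", "Hemisphere",
                 "Relationship"), collapse = "\t"))
    f <- utils::head(res$frequency, top)
    if (nrow(f) == 0) push("(no anomalies)")
    for (r in seq_len(nrow(f)))
      push(paste(f$n_patients[r], f$affiliation_a[r], f$region_a[r],
                 f$region_b[r], f$affiliation_b[r],
                 f$hemisphere_relation[r], f$relationship[r], sep = "\t"))
    push("")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
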