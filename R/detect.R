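#' Detect anomalous edges in one subject against a normative reference
#'
#' Scores every unordered region pair of one subject on the reference's
#' detection representation: `z = (x - mu) / sigma`. An edge is
#' `anomaly_low` when `z < -k_sigma` and `anomaly_high` when `z > k_sigma`
#' (strict inequalities: `|z| = k_sigma` exactly is `normal`). Edges excluded
#' by the reference's between-subject variance mask are `excluded`; edges with
#' zero normative standard deviation are `degenerate`; neither carries a
#' z-score. Functional subjects are embedded at the reference's stored
#' geometric mean — the reference point is never re-fit.
#'
#' @param subject a `conn_matrix` of the reference's modality.
#' @param reference a `normative_reference` from [fit_normative()].
#' @param k_sigma detection threshold; defaults to the reference's.
#' @return an object of class `anomaly_matrix` with per-edge `status` and
#'   `zscore` vectors in canonical edge order.
#' @export
detect_anomalies <- function(subject, reference, k_sigma = NULL) {
  if (!inherits(subject, "conn_matrix")) stop("subject must be a conn_matrix")
  if (!inherits(reference, "normative_reference"))
    stop("reference must be a normative_reference")
  if (subject$modality != reference$modality)
    stop("modality mismatch: subject is ", subject$modality,
         ", reference is ", reference$modality)
  if (nrow(subject$values) != reference$n_regions)
    stop("shape mismatch: subject has ", nrow(subject$values),
         " regions, reference ", reference$n_regions)
  if (is.null(k_sigma)) k_sigma <- reference$k_sigma
  if (k_sigma <= 0) stop("k_sigma must be positive")

  x <- representation_values(subject$values, reference$representation,
                             reference$reference_matrix, reference$shrinkage)
  z <- (x - reference$mu) / reference$sigma
  status <- rep("normal", length(z))
  status[z < -k_sigma] <- "anomaly_low"
  status[z > k_sigma] <- "anomaly_high"
  status[reference$degenerate] <- "degenerate"
  status[reference$excluded] <- "excluded"
  z[reference$degenerate | reference$excluded] <- NA_real_
  structure(list(
    subject_id = subject$subject_id, modality = subject$modality,
    status = status, zscore = z, k_sigma = k_sigma,
    n_regions = reference$n_regions, region_names = reference$region_names,
    edge_i = reference$edge_i, edge_j = reference$edge_j),
    class = "anomaly_matrix")
}

#' @export
print.anomaly_matrix <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("normal", "anomaly_low",
                                           "anomaly_high", "excluded",
                                           "degenerate")))
  cat("Anomaly matrix:", x$subject_id, "(", x$modality, ", ",
      x$k_sigma, "sigma )\n")
  cat(" ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Score a cohort of subjects against one normative reference
#'
#' Applies [detect_anomalies()] to each subject in order, logging per-subject
#' anomaly counts.
#'
#' @param subjects non-empty list of `conn_matrix` objects.
#' @param reference a `normative_reference`.
#' @param k_sigma detection threshold; defaults to the reference's.
#' @param verbose emit one log line per subject (default `FALSE`).
#' @return list of `anomaly_matrix` objects, order preserved.
#' @export
cohort_detect <- function(subjects, reference, k_sigma = NULL, verbose = FALSE) {
  if (!is.list(subjects) || length(subjects) == 0)
    stop("subjects must be a non-empty list")
  lapply(subjects, function(s) {
    am <- tryCatch(detect_anomalies(s, reference, k_sigma),
                   error = function(e) stop("subject '", s$subject_id, "': ",
                                            conditionMessage(e), call. = FALSE))
    if (verbose)
      message("subject ", am$subject_id, ": ",
              sum(am$status %in% c("anomaly_low", "anomaly_high")),
              " anomalous edges (", sum(am$status == "anomaly_low"), " low, ",
              sum(am$status == "anomaly_high"), " high)")
    am
  })
}

#' @rdname detect_anomalies
#' @param object a `normative_reference`.
#' @param newdata a `conn_matrix` or a list of them.
#' @param ... passed on (`k_sigma`).
#' @export
predict.normative_reference <- function(object, newdata, ...) {
  if (inherits(newdata, "conn_matrix")) detect_anomalies(newdata, object, ...)
  else cohort_detect(newdata, object, ...)
}

#' Anomaly matrix as a long-format data frame
#'
#' @param x an `anomaly_matrix`.
#' @param ... unused.
#' @return data frame with columns `subject`, `region_a`, `region_b`,
#'   `modality`, `zscore`, `status`.
#' @export
as.data.frame.anomaly_matrix <- function(x, ...) {
  data.frame(subject = x$subject_id,
             region_a = x$region_names[x$edge_i],
             region_b = x$region_names[x$edge_j],
             modality = x$modality, zscore = x$zscore, status = x$status,
             stringsAsFactors = FALSE)
}

# Square status matrix (region x region); diagonal is "excluded" (self-edges
# are never assessed).
status_matrix <- function(am) {
  n <- am$n_regions
  m <- matrix("excluded", n, n,
              dimnames = list(am$region_names, am$region_names))
  idx <- cbind(am$edge_i, am$edge_j)
  m[idx] <- am$status
  m[idx[, c(2, 1)]] <- am$status
  m
}
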