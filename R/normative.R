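#' Correlation matrix from a regional time-series matrix
#'
#' Computes the product-moment correlation matrix of region-averaged BOLD time
#' series (rows = time points, columns = regions). Over the default 379-region
#' atlas the full square matrix has 379^2 = 143,641 entries.
#'
#' @param series numeric matrix, time x region, with at least 2 rows; column
#'   names (if present) are carried over as region names.
#' @param subject_id subject identifier.
#' @return a functional `conn_matrix`.
#' @export
fc_from_timeseries <- function(series, subject_id = "subject") {
  if (!is.matrix(series) || !is.numeric(series))
    stop("series must be a numeric matrix (time x region)")
  if (nrow(series) < 2) stop("need at least 2 time points, got ", nrow(series))
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("region(s) with zero variance: ", paste(bad, collapse = ", "))
  }
  C <- stats::cor(series)
  conn_matrix(C, "functional", subject_id = subject_id)
}

#' Mask the highest between-subject-variance edges
#'
#' Marks exactly `floor(fraction * n_edges)` edges for exclusion: those with
#' the highest between-subject variance in the control cohort, ties broken by
#' ascending edge index (stable).
#'
#' @param variances numeric vector of per-edge variances.
#' @param fraction fraction of edges to exclude, in \[0, 1).
#' @return logical vector, `TRUE` = excluded.
#' @export
variance_exclusion_mask <- function(variances, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction < 0 ||
      fraction >= 1)
    stop("fraction must be a single number in [0, 1)")
  n <- length(variances)
  k <- floor(fraction * n)
  mask <- rep(FALSE, n)
  if (k > 0) {
    ord <- order(-variances, seq_len(n))   # highest variance first, stable
    mask[ord[seq_len(k)]] <- TRUE
  }
  mask
}

# Per-edge values of one subject on the detection representation.
representation_values <- function(values, representation, reference_matrix = NULL,
                                  shrinkage = 1e-3) {
  switch(representation,
    log1p_count = edge_values(log1p(values)),
    raw_count = edge_values(values),
    tangent = edge_values(tangent_embed(prep_fc(values, shrinkage),
                                        reference_matrix)),
    stop("unknown representation '", representation, "'"))
}

#' Fit a normative connectivity reference from a control cohort
#'
#' Estimates, for every unordered off-diagonal region pair ("edge"), the
#' normative mean and standard deviation of the detection representation over
#' a cohort of healthy controls, and masks out the fraction of edges with the
#' highest between-subject variance.
#'
#' Structural matrices are represented as `log1p` of the streamline counts
#' (`representation = "raw_count"` uses the counts untransformed). Functional
#' correlation matrices are first shrunk toward the identity
#' (`(1 - shrinkage) C + shrinkage I`), the cohort's affine-invariant geometric
#' mean is computed, and each subject is embedded in the tangent space at that
#' mean (whitening + matrix logarithm); per-edge statistics are taken on the
#' tangent coefficients.
#'
#' Per-edge standard deviations use the sample convention (denominator
#' `n - 1`). Edges with zero standard deviation are marked degenerate and are
#' never flagged in detection. Exactly `floor(exclusion_fraction * n_edges)`
#' edges are excluded, ties broken by ascending edge index.
#'
#' @param cohort list of `conn_matrix` objects of a single modality (>= 3).
#' @param exclusion_fraction fraction of highest-variance edges to exclude
#'   (default 1/3).
#' @param k_sigma default detection threshold in normative standard deviations
#'   (default 3).
#' @param representation `NULL` (modality default: `log1p_count` for
#'   structural, `tangent` for functional), or one of `"log1p_count"`,
#'   `"raw_count"`, `"tangent"`.
#' @param shrinkage identity-shrinkage weight applied to functional matrices
#'   before any matrix logarithm (default 1e-3).
#' @param mean_type reference-point algorithm for the tangent embedding:
#'   `"karcher"` (affine-invariant fixed point, default) or `"log_euclidean"`.
#' @param tol,max_iter convergence controls for the geometric mean.
#' @param atlas optional `conn_atlas`; defaults to region names taken from the
#'   first matrix.
#' @return an object of class `normative_reference` with per-edge `mu`,
#'   `sigma`, `variance`, `variance_rank` (1 = highest), `excluded` and
#'   `degenerate` vectors, the SPD `reference_matrix` (functional only), and
#'   the fitting parameters.
#' @export
fit_normative <- function(cohort, exclusion_fraction = 1/3, k_sigma = 3,
                          representation = NULL, shrinkage = 1e-3,
                          mean_type = c("karcher", "log_euclidean"),
                          tol = 1e-8, max_iter = 50, atlas = NULL) {
  mean_type <- match.arg(mean_type)
  if (!is.list(cohort) || length(cohort) < 3)
    stop("need a control cohort of at least 3 subjects, got ",
         if (is.list(cohort)) length(cohort) else 0)
  if (!all(vapply(cohort, inherits, TRUE, "conn_matrix")))
    stop("cohort must be a list of conn_matrix objects")
  modality <- unique(vapply(cohort, function(s) s$modality, ""))
  if (length(modality) != 1)
    stop("cohort mixes modalities: ", paste(modality, collapse = ", "))
  n <- nrow(cohort[[1]]$values)
  if (any(vapply(cohort, function(s) nrow(s$values), 0L) != n))
    stop("cohort matrices differ in dimension")
  if (exclusion_fraction < 0 || exclusion_fraction >= 1)
    stop("exclusion_fraction must be in [0, 1)")
  if (k_sigma <= 0) stop("k_sigma must be positive")
  if (is.null(representation))
    representation <- if (modality == "structural") "log1p_count" else "tangent"
  if (modality == "structural" && representation == "tangent")
    stop("tangent representation applies to functional matrices only")
  if (modality == "functional" && representation != "tangent")
    stop("functional cohorts use the tangent representation")

  region_names <- rownames(cohort[[1]]$values)
  if (is.null(region_names)) region_names <- sprintf("region_%03d", seq_len(n))

  reference_matrix <- NULL
  if (representation == "tangent") {
    shrunk <- lapply(cohort, function(s) prep_fc(s$values, shrinkage))
    reference_matrix <- geometric_mean_spd(shrunk, tol = tol,
                                           max_iter = max_iter,
                                           type = mean_type)
    X <- t(vapply(shrunk,
                  function(m) edge_values(tangent_embed(m, reference_matrix)),
                  numeric(n_edges(n))))
  } else {
    X <- t(vapply(cohort,
                  function(s) representation_values(s$values, representation),
                  numeric(n_edges(n))))
  }

  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)      # sample sd, denominator n - 1
  variance <- sigma^2
  ne <- n_edges(n)
  variance_rank <- integer(ne)
  variance_rank[order(-variance, seq_len(ne))] <- seq_len(ne)
  excluded <- variance_exclusion_mask(variance, exclusion_fraction)
  degenerate <- !is.finite(sigma) | sigma == 0

  pairs <- edge_pairs(n)
  structure(list(
    modality = modality, representation = representation,
    reference_matrix = reference_matrix,
    mu = mu, sigma = sigma, variance = variance,
    variance_rank = variance_rank,
    excluded = excluded, degenerate = degenerate,
    n_controls = length(cohort), n_regions = n,
    region_names = region_names,
    edge_i = pairs[, 1], edge_j = pairs[, 2],
    exclusion_fraction = exclusion_fraction, k_sigma = k_sigma,
    shrinkage = shrinkage, mean_type = mean_type),
    class = "normative_reference")
}

#' @export
print.normative_reference <- function(x, ...) {
  cat("Normative connectivity reference (", x$modality, ", ",
      x$representation, ")\n", sep = "")
  cat("  controls:", x$n_controls, "  regions:", x$n_regions,
      "  edges:", length(x$mu), "\n")
  cat("  excluded (top ", format(x$exclusion_fraction), " variance): ",
      sum(x$excluded), "  degenerate: ", sum(x$degenerate & !x$excluded),
      "\n", sep = "")
  cat("  detection threshold: ", x$k_sigma, " sigma\n", sep = "")
  invisible(x)
}

#' @export
summary.normative_reference <- function(object, ...) {
  retained <- !object$excluded & !object$degenerate
  out <- list(
    modality = object$modality,
    n_controls = object$n_controls,
    n_regions = object$n_regions,
    n_edges = length(object$mu),
    n_excluded = sum(object$excluded),
    n_degenerate = sum(object$degenerate & !object$excluded),
    n_retained = sum(retained),
    sigma_quartiles = stats::quantile(object$sigma[retained],
                                      c(0.25, 0.5, 0.75)))
  class(out) <- "summary.normative_reference"
  out
}

#' @export
print.summary.normative_reference <- function(x, ...) {
  cat("Normative reference summary (", x$modality, ")\n", sep = "")
  cat("  controls:", x$n_controls, " regions:", x$n_regions,
      " edges:", x$n_edges, "\n")
  cat("  retained:", x$n_retained, " excluded:", x$n_excluded,
      " degenerate:", x$n_degenerate, "\n")
  cat("  retained-edge sigma quartiles:",
      paste(format(x$sigma_quartiles, digits = 3), collapse = " / "), "\n")
  invisible(x)
}

#' Per-edge normative moments
#'
#' @param object a `normative_reference`.
#' @param ... unused.
#' @return data frame with one row per unordered region pair: `region_a`,
#'   `region_b`, `mu`, `sigma`, `variance`, `variance_rank`, `excluded`,
#'   `degenerate`.
#' @export
coef.normative_reference <- function(object, ...) {
  data.frame(
    region_a = object$region_names[object$edge_i],
    region_b = object$region_names[object$edge_j],
    mu = object$mu, sigma = object$sigma, variance = object$variance,
    variance_rank = object$variance_rank,
    excluded = object$excluded, degenerate = object$degenerate,
    stringsAsFactors = FALSE)
}
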