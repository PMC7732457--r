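#' Construct a subject connectivity matrix
#'
#' Wraps one subject's symmetric region-by-region matrix, tagged structural
#' (non-negative streamline counts, zero diagonal) or functional (correlation
#' coefficients in \[-1, 1\], unit diagonal). Matrices are symmetrized by
#' averaging; asymmetry beyond `1e-8` is an error. Row/column order must match
#' the atlas.
#'
#' @param values square numeric matrix with region-name dimnames (or none, in
#'   which case atlas order is assumed).
#' @param modality `"structural"` or `"functional"`.
#' @param subject_id subject identifier string.
#' @param atlas a `conn_atlas` the matrix is aligned to.
#' @return an object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, modality = c("structural", "functional"),
                        subject_id = "subject", atlas = NULL) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || nrow(values) != ncol(values) || !is.numeric(values))
    stop("values must be a square numeric matrix")
  if (anyNA(values)) stop("values contain NA")
  if (!is.null(atlas)) {
    if (nrow(values) != n_regions(atlas))
      stop("matrix dimension ", nrow(values), " does not match atlas size ",
           n_regions(atlas))
    if (!is.null(rownames(values)) &&
        !identical(rownames(values), atlas$regions$name))
      stop("matrix row names are not in atlas order")
    dimnames(values) <- list(atlas$regions$name, atlas$regions$name)
  }
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8)
    stop("matrix for subject '", subject_id, "' is asymmetric (max |M - t(M)| = ",
         format(asym), ")")
  values <- (values + t(values)) / 2
  if (modality == "structural") {
    if (min(values) < 0) stop("structural counts must be non-negative")
    diag(values) <- 0
  } else {
    if (max(abs(values)) > 1 + 1e-8)
      stop("functional values must lie in [-1, 1]")
    values[values > 1] <- 1
    values[values < -1] <- -1
    diag(values) <- 1
  }
  structure(list(subject_id = subject_id, modality = modality, values = values),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat("Connectivity matrix:", x$subject_id, "(", x$modality, ")",
      nrow(x$values), "x", ncol(x$values), "\n")
  invisible(x)
}
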