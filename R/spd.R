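# Symmetric-matrix functional calculus via eigendecomposition. All inputs are
# symmetrized first; SPD checks are on the eigenvalues.

sym_part <- function(m) (m + t(m)) / 2

sym_fun <- function(m, f) {
  e <- eigen(sym_part(m), symmetric = TRUE)
  sym_part(e$vectors %*% (f(e$values) * t(e$vectors)))
}

check_spd <- function(m, label = "matrix", tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(label, " must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8)
    stop(label, " is not symmetric")
  ev <- eigen(sym_part(m), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev)))
    stop(label, " is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  invisible(ev)
}

spd_sqrt <- function(m) sym_fun(m, sqrt)
spd_inv_sqrt <- function(m) sym_fun(m, function(x) 1 / sqrt(x))
spd_logm <- function(m) sym_fun(m, log)
sym_expm <- function(m) sym_fun(m, exp)

#' Affine-invariant (Karcher) geometric mean of SPD matrices
#'
#' Computes the Fréchet mean of symmetric positive-definite matrices under the
#' affine-invariant Riemannian metric by the standard fixed-point iteration
#' \eqn{G \leftarrow G^{1/2} \exp\{\tfrac1N \sum_i \log(G^{-1/2} C_i G^{-1/2})\} G^{1/2}},
#' initialized at the arithmetic mean. Convergence is declared when the
#' Frobenius norm of the mean tangent update falls below `tol`.
#'
#' A `log_euclidean` mean (matrix exponential of the average matrix logarithm)
#' is available as a cheaper alternative.
#'
#' @param matrices list of SPD matrices of a common dimension.
#' @param tol convergence tolerance on the Frobenius norm of the update.
#' @param max_iter maximum fixed-point iterations.
#' @param type `"karcher"` (default) or `"log_euclidean"`.
#' @return the mean SPD matrix.
#' @export
geometric_mean_spd <- function(matrices, tol = 1e-8, max_iter = 50,
                               type = c("karcher", "log_euclidean")) {
  type <- match.arg(type)
  stopifnot(is.list(matrices), length(matrices) >= 1)
  for (i in seq_along(matrices)) check_spd(matrices[[i]], paste0("matrix ", i))
  n <- nrow(matrices[[1]])
  if (any(vapply(matrices, nrow, 0L) != n)) stop("matrices differ in dimension")
  if (length(matrices) == 1) return(sym_part(matrices[[1]]))
  if (type == "log_euclidean") {
    s <- Reduce(`+`, lapply(matrices, spd_logm)) / length(matrices)
    return(sym_expm(s))
  }
  g <- sym_part(Reduce(`+`, matrices) / length(matrices))
  for (iter in seq_len(max_iter)) {
    w <- spd_inv_sqrt(g)
    s <- Reduce(`+`, lapply(matrices, function(c) spd_logm(w %*% c %*% w))) /
      length(matrices)
    resid <- sqrt(sum(s^2))
    if (resid < tol) return(g)
    gh <- spd_sqrt(g)
    g <- sym_part(gh %*% sym_expm(s) %*% gh)
  }
  stop("geometric mean did not converge in ", max_iter,
       " iterations (last residual ", format(resid), ")")
}

#' Tangent-space embedding of an SPD matrix at a reference point
#'
#' Whitens `C` by the reference and takes the matrix logarithm:
#' \eqn{T = \log(\bar C^{-1/2} C \bar C^{-1/2})}. The result is symmetric; the
#' embedding is inverted exactly by [tangent_invert()].
#'
#' @param C an SPD matrix (e.g., a shrunk correlation matrix).
#' @param reference the SPD reference point (e.g., the cohort geometric mean).
#' @return the symmetric matrix of tangent coefficients.
#' @export
tangent_embed <- function(C, reference) {
  if (!all(dim(C) == dim(reference))) stop("shape mismatch between C and reference")
  check_spd(C, "C")
  check_spd(reference, "reference")
  w <- spd_inv_sqrt(reference)
  spd_logm(w %*% C %*% w)
}

#' Invert a tangent-space embedding
#'
#' @param T a symmetric tangent matrix as produced by [tangent_embed()].
#' @param reference the SPD reference point used for the embedding.
#' @return the reconstructed SPD matrix.
#' @export
tangent_invert <- function(T, reference) {
  if (!all(dim(T) == dim(reference))) stop("shape mismatch between T and reference")
  check_spd(reference, "reference")
  gh <- spd_sqrt(reference)
  sym_part(gh %*% sym_expm(sym_part(T)) %*% gh)
}

# Prepare a functional correlation matrix for tangent embedding: symmetrize,
# shrink toward the identity, and floor tiny/negative eigenvalues at the
# shrinkage level (finite runs and planted perturbations can leave the matrix
# numerically indefinite).
prep_fc <- function(C, shrinkage = 1e-3) {
  m <- (1 - shrinkage) * sym_part(C) + shrinkage * diag(nrow(C))
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < shrinkage)
    m <- sym_part(e$vectors %*% (pmax(e$values, shrinkage) * t(e$vectors)))
  m
}
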