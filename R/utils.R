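# Internal linear-algebra helpers shared across the package.

# Upper-triangle (row-major) half-vectorization index for an L x L matrix.
# Returned as a 2-column matrix of (row, col) pairs with row <= col,
# ordered by row then column: (1,1),(1,2),...,(1,L),(2,2),...
vech_index <- function(L) {
  idx <- which(upper.tri(diag(L), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- NULL
  idx
}

# vech(M): upper triangle, row-major.
vech <- function(M) {
  idx <- vech_index(nrow(M))
  unname(M[idx])
}

# Inverse of vech for a symmetric matrix.
unvech <- function(v, L) {
  M <- matrix(0, L, L)
  idx <- vech_index(L)
  M[idx] <- v
  M[idx[, c(2, 1), drop = FALSE]] <- v
  M
}

# Weights turning vech into a minimal inner-product coordinate: 1 on the
# diagonal, 2 off it, so sum(w * vech(A) * vech(B)) = tr(A B) for symmetric A, B.
vech_weights <- function(L) {
  idx <- vech_index(L)
  ifelse(idx[, 1] == idx[, 2], 1, 2)
}

# Symmetrize and verify positive definiteness: the smallest eigenvalue must be
# positive and exceed 1e-10 relative to the largest (so near-deterministic but
# well-scaled covariances pass). Errors rather than projecting.
check_spd <- function(M, tol = 1e-10, what = "matrix") {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || min(ev) <= tol * max(ev)) {
    stop(sprintf("%s is not positive definite (min eigenvalue %.3e)", what, min(ev)),
         call. = FALSE)
  }
  M
}

is_spd <- function(M, tol = 1e-10) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > 0 && min(ev) > tol * max(ev)
}

# Draw n standard-normal vectors as an n x L matrix.
rnorm_mat <- function(n, L) matrix(stats::rnorm(n * L), n, L)

`%||%` <- function(a, b) if (is.null(a)) b else a
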