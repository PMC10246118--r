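#' Constant base measure exponential families
#'
#' Family objects describe a minimal exponential family with density
#' `h * exp(lambda . t(z) - A(lambda))` whose base measure `h` does not depend
#' on `z`. All natural and mean parameters are handled as flat numeric vectors
#' of length `dim_lambda`; the plain Euclidean inner product of a natural and a
#' mean vector equals `lambda . t(z)` in expectation, so textbook identities
#' (`mu = grad A`, the KL/entropy formulas) hold coordinate-wise.
#'
#' Shipped families:
#' * `gaussian_family(L)` — multivariate normal; `t(z) = (z, vech(z z^T))`.
#'   Layout: `lambda = c(P^{-1} m, vech(-P^{-1}/2))` with `vech` the row-major
#'   upper triangle. The mean vector stores `(m, w * vech(P + m m^T))` where
#'   `w` doubles the off-diagonal entries, making the flat dot product equal
#'   to `lambda1 . z + tr(Lambda2 z z^T)`.
#' * `cb_family(L)` — factorized continuous Bernoulli on `[0,1]^L`; `t(z) = z`,
#'   one real natural parameter per coordinate (any real value is valid).
#' * `gamma_family(L)` — factorized Gamma on the positive reals;
#'   `t(z) = (log z, z)` per coordinate, layout `c(alpha - 1, -beta)` as two
#'   blocks of length `L`. Valid iff `lambda1 > -1` and `lambda2 < 0`.
#' * `bernoulli_family(L)` — factorized Bernoulli on `{0,1}^L` (used for
#'   conjugacy checks).
#'
#' @param L Latent dimension (positive integer).
#' @return An object of class `ef_family`.
#' @examples
#' fam <- gaussian_family(2)
#' lam <- gaussian_natural(c(0, 0), diag(2))
#' natural_to_mean(fam, lam)
#' @name ef_family
NULL

new_ef_family <- function(name, L, dim_lambda, support, class) {
  structure(
    list(name = name, dim_z = as.integer(L),
         dim_lambda = as.integer(dim_lambda), support = support),
    class = c(class, "ef_family")
  )
}

#' @rdname ef_family
#' @export
gaussian_family <- function(L) {
  fam <- new_ef_family("gaussian", L, L + L * (L + 1) / 2, "real^L",
                       "gaussian_family")
  fam$vech_idx <- vech_index(L)
  fam$vech_w <- vech_weights(L)
  fam
}

#' @rdname ef_family
#' @export
cb_family <- function(L) {
  new_ef_family("continuous_bernoulli", L, L, "[0,1]^L", "cb_family")
}

#' @rdname ef_family
#' @export
gamma_family <- function(L) {
  new_ef_family("gamma", L, 2 * L, "positive^L", "gamma_family")
}

#' @rdname ef_family
#' @export
bernoulli_family <- function(L) {
  new_ef_family("bernoulli", L, L, "{0,1}^L", "bernoulli_family")
}

#' @export
print.ef_family <- function(x, ...) {
  cat(sprintf("<ef_family: %s, dim_z = %d, dim_lambda = %d, support = %s>\n",
              x$name, x$dim_z, x$dim_lambda, x$support))
  invisible(x)
}

same_family <- function(f1, f2) {
  identical(f1$name, f2$name) && identical(f1$dim_z, f2$dim_z)
}

check_lambda <- function(family, lambda) {
  if (length(lambda) != family$dim_lambda) {
    stop(sprintf("natural parameter has length %d, family '%s' expects %d",
                 length(lambda), family$name, family$dim_lambda), call. = FALSE)
  }
  if (!all(is.finite(lambda))) {
    stop("natural parameter contains non-finite values", call. = FALSE)
  }
  invisible(lambda)
}

# ---- generics ---------------------------------------------------------------

#' Exponential-family operations
#'
#' Core coordinate maps and functionals of a family: the log-partition
#' function `A(lambda)`, the bijective natural/mean maps `mu = grad A(lambda)`
#' and its inverse, i.i.d. sampling, KL divergence
#' `KL(q||p) = (lambda_q - lambda_p) . mu_q - A(lambda_q) + A(lambda_p)`,
#' differential entropy, and pointwise log density.
#'
#' @param family An [ef_family] object.
#' @param lambda,lambda_q,lambda_p Natural-parameter vectors.
#' @param mu Mean-parameter vector (expected sufficient statistics).
#' @param n Number of draws.
#' @param z Matrix of points (`n x dim_z`), or a single vector.
#' @return `log_partition`, `entropy`, `kl_divergence`: scalars.
#'   `natural_to_mean`, `mean_to_natural`: flat parameter vectors.
#'   `ef_sample`: an `n x dim_z` matrix. `ef_log_density`: a vector of length
#'   `n`. `ef_suffstat`: an `n x dim_lambda` matrix.
#' @name expfam-ops
NULL

#' @rdname expfam-ops
#' @export
log_partition <- function(family, lambda) UseMethod("log_partition")

#' @rdname expfam-ops
#' @export
natural_to_mean <- function(family, lambda) UseMethod("natural_to_mean")

#' @rdname expfam-ops
#' @export
mean_to_natural <- function(family, mu) UseMethod("mean_to_natural")

#' @rdname expfam-ops
#' @export
ef_sample <- function(family, lambda, n = 1) UseMethod("ef_sample")

#' @rdname expfam-ops
#' @export
ef_suffstat <- function(family, z) UseMethod("ef_suffstat")

# log of the (constant) base measure
log_h <- function(family) UseMethod("log_h")

# Hessian of A at lambda (Fisher information in natural coordinates);
# used by the CVI update to convert natural-gradient increments.
ef_fisher <- function(family, lambda) UseMethod("ef_fisher")

#' @rdname expfam-ops
#' @export
kl_divergence <- function(family, lambda_q, lambda_p) {
  check_lambda(family, lambda_q)
  check_lambda(family, lambda_p)
  mu_q <- natural_to_mean(family, lambda_q)
  sum((lambda_q - lambda_p) * mu_q) -
    log_partition(family, lambda_q) + log_partition(family, lambda_p)
}

#' @rdname expfam-ops
#' @export
ef_entropy <- function(family, lambda) {
  mu <- natural_to_mean(family, lambda)
  log_partition(family, lambda) - sum(lambda * mu) - log_h(family)
}

#' @rdname expfam-ops
#' @export
ef_log_density <- function(family, lambda, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  tz <- ef_suffstat(family, z)
  drop(log_h(family) + tz %*% lambda - log_partition(family, lambda))
}

# ---- Gaussian ---------------------------------------------------------------

#' Gaussian natural parameters from moments (and back)
#'
#' `gaussian_natural(m, P)` returns the flat natural vector
#' `c(P^{-1} m, vech(-P^{-1}/2))`; `gaussian_moments(family, lambda)` inverts
#' it, returning `list(m, P)`.
#'
#' @param m Mean vector.
#' @param P Covariance matrix (SPD).
#' @param family A `gaussian_family`.
#' @param lambda Flat natural vector.
#' @export
gaussian_natural <- function(m, P) {
  P <- check_spd(as.matrix(P), what = "covariance")
  Pinv <- solve(P)
  c(Pinv %*% m, vech(-Pinv / 2))
}

#' @rdname gaussian_natural
#' @export
gaussian_moments <- function(family, lambda) {
  check_lambda(family, lambda)
  L <- family$dim_z
  Lam2 <- unvech(lambda[-seq_len(L)], L)
  Prec <- check_spd(-2 * Lam2, what = "Gaussian natural precision")
  P <- solve(Prec)
  P <- (P + t(P)) / 2
  list(m = drop(P %*% lambda[seq_len(L)]), P = P)
}

#' @export
log_h.gaussian_family <- function(family) -family$dim_z / 2 * log(2 * pi)

#' @export
log_partition.gaussian_family <- function(family, lambda) {
  mo <- gaussian_moments(family, lambda)
  0.5 * sum(mo$m * solve(mo$P, mo$m)) + 0.5 * determinant(mo$P)$modulus[1]
}

#' @export
natural_to_mean.gaussian_family <- function(family, lambda) {
  mo <- gaussian_moments(family, lambda)
  c(mo$m, family$vech_w * vech(mo$P + tcrossprod(mo$m)))
}

#' @export
mean_to_natural.gaussian_family <- function(family, mu) {
  L <- family$dim_z
  m <- mu[seq_len(L)]
  S <- unvech(mu[-seq_len(L)] / family$vech_w, L)
  P <- check_spd(S - tcrossprod(m), what = "Gaussian mean-domain covariance")
  gaussian_natural(m, P)
}

#' @export
ef_sample.gaussian_family <- function(family, lambda, n = 1) {
  mo <- gaussian_moments(family, lambda)
  eps <- rnorm_mat(n, family$dim_z)
  sweep(eps %*% chol(mo$P), 2, mo$m, `+`)
}

#' @export
ef_suffstat.gaussian_family <- function(family, z) {
  n <- nrow(z)
  idx <- family$vech_idx
  t2 <- z[, idx[, 1], drop = FALSE] * z[, idx[, 2], drop = FALSE]
  cbind(z, sweep(t2, 2, family$vech_w, `*`))
}

#' @export
ef_fisher.gaussian_family <- function(family, lambda) {
  stop("Fisher information is not needed for the Gaussian CVI path", call. = FALSE)
}
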