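#' Variational prediction free energy and bound gap
#'
#' `free_energy()` evaluates the objective minimized by the variational
#' prediction step,
#' `F(lambda_bar) = -H(q_bar) - E_{q_bar} E_{q_prev} log p_theta(z_t | z_{t-1})`,
#' an upper bound on `KL(q_bar || E_{q_prev} p_theta)`. Its minimizer over the
#' family is the expected-natural-parameter solution returned by
#' [variational_predict()]; the function exists chiefly as an independent
#' numerical check of that optimality.
#'
#' `bound_gap()` evaluates the tightness gap between the two-step (predict
#' then update) ELBO and the single-step bound,
#' `Delta = E_{q_prev}[A(lambda_theta(z))] - A(lambda_bar_theta) >= 0`
#' (a Jensen gap, so nonnegative up to Monte-Carlo error). The returned scalar
#' carries attributes `"se"` (Monte-Carlo standard error) and `"n_mc"`.
#'
#' For both functions a fixed sample matrix `zs` may be supplied in place of
#' fresh draws, making the value deterministic in `lambda_bar` (useful when
#' optimizing over `lambda_bar` with common random numbers).
#'
#' @inheritParams evkf-steps
#' @param zs Optional pre-drawn sample matrix (`n_mc x L`) from the previous
#'   posterior.
#' @return Scalar.
#' @name evkf-bounds
NULL

# Row-wise log-partition over a matrix of natural parameters.
ef_log_partition_rows <- function(family, Lam) {
  if (inherits(family, "cb_family")) {
    rowSums(matrix(cb_logA(Lam), nrow(Lam), ncol(Lam)))
  } else if (inherits(family, "gamma_family")) {
    L <- family$dim_z
    a <- Lam[, seq_len(L), drop = FALSE] + 1
    b <- -Lam[, L + seq_len(L), drop = FALSE]
    rowSums(lgamma(a) - a * log(b))
  } else if (inherits(family, "gaussian_family")) {
    L <- family$dim_z
    lam2 <- Lam[, -seq_len(L), drop = FALSE]
    if (all(abs(sweep(lam2, 2, lam2[1, ], `-`)) < 1e-14)) {
      # common second block (fixed state noise): A = m' lam1 / 2 + log|P| / 2
      P <- solve(check_spd(-2 * unvech(lam2[1, ], L), what = "precision"))
      lam1 <- Lam[, seq_len(L), drop = FALSE]
      0.5 * rowSums((lam1 %*% P) * lam1) + 0.5 * determinant(P)$modulus[1]
    } else {
      apply(Lam, 1, function(l) log_partition(family, l))
    }
  } else {
    apply(Lam, 1, function(l) log_partition(family, l))
  }
}

#' @rdname evkf-bounds
#' @export
free_energy <- function(family, lambda_bar, lambda_prev, dyn, n_mc = 1e4,
                        zs = NULL) {
  check_lambda(family, lambda_bar)
  if (is.null(zs)) zs <- ef_sample(family, lambda_prev, n_mc)
  Lam <- eval_lambda(dyn, zs)
  lam_hat <- colMeans(Lam)
  A_bar <- mean(ef_log_partition_rows(family, Lam))
  mu_bar <- natural_to_mean(family, lambda_bar)
  # -H(q_bar) - E_qbar E_qprev log p = (lambda_bar - lam_hat).mu_bar
  #   - A(lambda_bar) + mean_i A(lambda_theta(z_i))   (base measures cancel)
  sum((lambda_bar - lam_hat) * mu_bar) -
    log_partition(family, lambda_bar) + A_bar
}

#' @rdname evkf-bounds
#' @export
bound_gap <- function(family, lambda_prev, dyn, n_mc = 1e4, zs = NULL) {
  if (is.null(zs)) zs <- ef_sample(family, lambda_prev, n_mc)
  Lam <- eval_lambda(dyn, zs)
  Ai <- ef_log_partition_rows(family, Lam)
  lam_bar <- colMeans(Lam)
  gap <- mean(Ai) - log_partition(family, lam_bar)
  structure(gap, se = stats::sd(Ai) / sqrt(nrow(zs)), n_mc = nrow(zs))
}

#' Single-step and two-step per-observation bounds
#'
#' `single_step_bound()` evaluates the one-shot variational bound
#' `M_t = E_q[log p(y|z)] - E_q[log q] - ... ` obtained by bounding the
#' marginalized transition directly with Jensen's inequality, namely
#' `E_q[log p(y|z)] + H(q) + E_q E_{q_prev}[log p_theta(z | z_prev)]`.
#' The two-step bound equals `elbo_value()` computed against
#' `q_bar = variational_predict(...)`; their difference is `bound_gap()`.
#'
#' @inheritParams evkf-bounds
#' @param lambda Natural parameters of the filtering posterior `q(z_t)`.
#' @param y Observation vector.
#' @param lik An `evkf_likelihood`.
#' @export
single_step_bound <- function(family, lambda, lambda_prev, dyn, y, lik,
                              n_mc = 1e4, zs = NULL) {
  if (is.null(zs)) zs <- ef_sample(family, lambda_prev, n_mc)
  Lam <- eval_lambda(dyn, zs)
  lam_hat <- colMeans(Lam)
  A_bar <- mean(ef_log_partition_rows(family, Lam))
  mu <- natural_to_mean(family, lambda)
  cross <- log_h(family) + sum(lam_hat * mu) - A_bar
  expected_loglik(lik, family, lambda, y) + ef_entropy(family, lambda) + cross
}
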