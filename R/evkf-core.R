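#' Variational prediction, correction, and update steps
#'
#' The online filter alternates four operations, all in natural-parameter
#' coordinates of a shared constant base measure exponential family:
#'
#' 1. `variational_predict()` — the variational analogue of the Kalman
#'    predict step. The KL-optimal prediction `q_bar` within the family has
#'    natural parameters equal to the *expected dynamics natural parameters*
#'    under the previous filtering posterior,
#'    `lambda_bar = E_q[lambda_theta(z_{t-1})]`, computed exactly where the
#'    expectation is affine in the sufficient statistics (linear-Gaussian,
#'    constant maps) and by Monte Carlo otherwise.
#' 2. `predict_correction()` — the predict step above propagates no
#'    uncertainty through state-independent natural-parameter blocks and so
#'    underestimates the predictive variance. For Gaussian families the
#'    EKF-like fix inflates the covariance by `M P M'` with `M` the Jacobian
#'    of the conditional-mean map at the previous mean; for the linear model
#'    this reproduces the exact Kalman prediction covariance `Q + A P A'`.
#'    For Gamma families the variance is moment-matched to a Monte-Carlo
#'    law-of-total-variance estimate; for the continuous Bernoulli the single
#'    natural parameter pins mean and variance jointly, so the correction is
#'    a documented pass-through.
#' 3. `conjugate_update()` — exact Bayes update when the likelihood is
#'    conjugate (Gaussian latent + Gaussian observation):
#'    `lambda = lambda_bar + (C'R^{-1}(y-b), -C'R^{-1}C/2)`.
#' 4. `cvi_update()` — natural-gradient (conjugate computation VI) ascent of
#'    the per-step ELBO `E_q[log p(y|z)] - KL(q || q_bar)` for non-conjugate
#'    pairs; one step with `beta = 1` reproduces the conjugate update when
#'    conjugacy holds. Iterations that leave the natural domain are
#'    backtracked by halving the step.
#'
#' @param family An [ef_family] shared by `q`, `q_bar` and the dynamics.
#' @param lambda_prev,lambda_bar Natural parameters of the previous filtering
#'   posterior and of the prediction.
#' @param dyn An `evkf_dynamics` object over the same family.
#' @param n_mc Monte-Carlo sample count for the prediction expectation.
#' @param mode `"auto"` uses the closed form when the dynamics provide one,
#'   `"exact"` requires it, `"mc"` forces Monte Carlo.
#' @param y One observation vector.
#' @param lik An `evkf_likelihood`.
#' @param iters,beta CVI iteration count and step size in `(0, 1]`.
#' @return A natural-parameter vector (`cvi_update`: with attribute `"elbo"`,
#'   the achieved value of the per-step objective).
#' @name evkf-steps
NULL

lambda_valid <- function(family, lambda) {
  !inherits(tryCatch(log_partition(family, lambda), error = identity), "error")
}

#' @rdname evkf-steps
#' @export
variational_predict <- function(family, lambda_prev, dyn, n_mc = 64,
                                mode = c("auto", "exact", "mc")) {
  mode <- match.arg(mode)
  if (!same_family(family, dyn$family)) {
    stop("dynamics family does not match the filtering family", call. = FALSE)
  }
  check_lambda(family, lambda_prev)
  if (mode != "mc") {
    ex <- expected_lambda_exact(dyn, lambda_prev)
    if (!is.null(ex)) return(ex)
    if (mode == "exact") {
      stop("no closed-form expected natural parameters for this dynamics class",
           call. = FALSE)
    }
  }
  zs <- ef_sample(family, lambda_prev, n_mc)
  lam_bar <- colMeans(eval_lambda(dyn, zs))
  if (!lambda_valid(family, lam_bar)) {
    stop(paste0("Monte-Carlo averaged natural parameters left the valid domain ",
                "(n_mc = ", n_mc, "); the dynamics map may be pathological"),
         call. = FALSE)
  }
  lam_bar
}

#' @rdname evkf-steps
#' @export
predict_correction <- function(family, lambda_bar, lambda_prev, dyn, n_mc = 256) {
  if (inherits(family, "gaussian_family")) {
    prev <- gaussian_moments(family, lambda_prev)
    bar <- gaussian_moments(family, lambda_bar)
    M <- mean_jacobian(dyn, prev$m)
    gaussian_natural(bar$m, bar$P + M %*% prev$P %*% t(M))
  } else if (inherits(family, "gamma_family")) {
    L <- family$dim_z
    zs <- ef_sample(family, lambda_prev, n_mc)
    lam <- eval_lambda(dyn, zs)
    a <- lam[, seq_len(L), drop = FALSE] + 1
    b <- -lam[, L + seq_len(L), drop = FALSE]
    cond_mean <- a / b
    cond_var <- a / b^2
    v_tot <- colMeans(cond_var) + apply(cond_mean, 2, stats::var)
    mu <- natural_to_mean(family, lambda_bar)
    m_bar <- mu[L + seq_len(L)]
    alpha <- m_bar^2 / v_tot
    beta <- m_bar / v_tot
    c(alpha - 1, -beta)
  } else if (inherits(family, "cb_family")) {
    # the CB natural parameter fixes mean and variance jointly; no widening
    # can preserve the predictive mean, so the correction is the identity
    lambda_bar
  } else {
    stop("variance correction is not available for family '", family$name, "'",
         call. = FALSE)
  }
}

#' @rdname evkf-steps
#' @export
conjugate_update <- function(family, lambda_bar, y, lik) {
  if (!(inherits(family, "gaussian_family") && lik$kind == "gaussian")) {
    stop("no conjugate update for this (family, likelihood) pair; use cvi_update()",
         call. = FALSE)
  }
  CRinv <- t(lik$C) %*% lik$Rinv
  inc2 <- -0.5 * CRinv %*% lik$C
  lambda_bar + c(CRinv %*% (y - lik$b), vech((inc2 + t(inc2)) / 2))
}

#' @rdname evkf-steps
#' @export
cvi_update <- function(family, lambda_bar, y, lik, iters = 10, beta = 0.5) {
  check_lambda(family, lambda_bar)
  lam <- lambda_bar
  for (k in seq_len(iters)) {
    g <- expected_loglik_grad_mu(lik, family, lam, y)
    target <- lambda_bar + g
    step <- beta
    repeat {
      cand <- (1 - step) * lam + step * target
      if (lambda_valid(family, cand)) break
      step <- step / 2
      if (step < beta / 2^20) {
        stop("CVI step left the natural-parameter domain and backtracking failed",
             call. = FALSE)
      }
    }
    lam <- cand
  }
  structure(lam, elbo = elbo_value(family, lam, lambda_bar, y, lik))
}

#' Per-step evidence lower bound
#'
#' The variational update objective
#' `E_q[log p(y|z)] - KL(q(.; lambda) || q_bar(.; lambda_bar))`, evaluated in
#' closed form for the shipped (family, likelihood) pairs.
#'
#' @inheritParams evkf-steps
#' @param lambda Natural parameters of the candidate posterior `q`.
#' @return Scalar bound value.
#' @export
elbo_value <- function(family, lambda, lambda_bar, y, lik) {
  expected_loglik(lik, family, lambda, y) -
    kl_divergence(family, lambda, lambda_bar)
}
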