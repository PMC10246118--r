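#' Evaluation metrics
#'
#' The four quantities used to score a filtering run against ground truth:
#'
#' * `filtering_log_density()` — temporal average log density of the inferred
#'   filtering distributions evaluated at the true latent trajectory,
#'   `T^{-1} sum_t log q(z_t^true; lambda_t)`. Higher is better.
#' * `dynamics_kl()` — local fidelity of a learned transition model: average
#'   KL from the *learned* one-step conditional to the *true* one,
#'   `S^{-1} sum_i KL( p_learned(. | Z_i) || p_true(. | Z_i) )`, over points
#'   `Z_i` sampled around the attractor manifold (attractor points plus
#'   Gaussian jitter). Note the learned model is the first KL argument.
#' * `chamfer()` / `sym_log_chamfer()` — global attractor-geometry
#'   discrepancy between two point sets; `chamfer` already contains both
#'   directional nearest-neighbour sums
#'   (`|S1|^{-1} sum min ||x-y||^2 + |S2|^{-1} sum min ||y-x||^2`), making the
#'   symmetrized wrapper `log( (chamfer(s1,s2) + chamfer(s2,s1)) / 2 )`
#'   idempotent up to the set-size weights; identical sets give `-Inf`
#'   (log of zero), returned as is and documented as the sentinel.
#' * `rmse()` — root mean squared error between filtered means and true
#'   latents over all `T x L` entries.
#'
#' @param lambdas `T x dim_lambda` matrix of filtering natural parameters
#'   (e.g. the `lambda` element of an `evkf_fit`), or an `evkf_fit`.
#' @param family The filtering [ef_family] (ignored when an `evkf_fit` is
#'   given).
#' @param zs_true `T x L` matrix (or `latents` tibble) of true states.
#' @param true_dyn,learned_dyn Two `evkf_dynamics` over the same family.
#' @param attractor `n x L` matrix of attractor points (see
#'   [attractor_points()]).
#' @param perturb_scale Standard deviation of the Gaussian jitter applied to
#'   the attractor points.
#' @param s1,s2 Point-set matrices (`n x d`, same `d`).
#' @param means `T x L` matrix (or tibble with `m*` columns) of filtered means.
#' @return Scalars.
#' @name metrics
NULL

truth_matrix <- function(zs_true) {
  if (is.data.frame(zs_true)) {
    zs_true <- as.matrix(zs_true[setdiff(names(zs_true), "t")])
  }
  as.matrix(zs_true)
}

#' @rdname metrics
#' @export
filtering_log_density <- function(lambdas, zs_true, family = NULL) {
  if (inherits(lambdas, "evkf_fit")) {
    family <- lambdas$family
    lambdas <- lambdas$lambda
  }
  zs_true <- truth_matrix(zs_true)
  if (nrow(lambdas) != nrow(zs_true)) {
    stop("posterior sequence and truth have different lengths", call. = FALSE)
  }
  ld <- vapply(seq_len(nrow(lambdas)), function(t) {
    ef_log_density(family, lambdas[t, ], zs_true[t, , drop = FALSE])
  }, numeric(1))
  mean(ld)
}

#' @rdname metrics
#' @export
dynamics_kl <- function(true_dyn, learned_dyn, attractor, perturb_scale = 0.1) {
  if (!same_family(true_dyn$family, learned_dyn$family)) {
    stop("dynamics families do not match", call. = FALSE)
  }
  pts <- truth_matrix(attractor)
  Z <- pts + perturb_scale * rnorm_mat(nrow(pts), ncol(pts))
  if (inherits(true_dyn$family, "cb_family")) {
    Z <- pmin(pmax(Z, 1e-4), 1 - 1e-4)
  }
  lam_learned <- eval_lambda(learned_dyn, Z)
  lam_true <- eval_lambda(true_dyn, Z)
  fam <- true_dyn$family
  kls <- vapply(seq_len(nrow(Z)), function(i) {
    kl_divergence(fam, lam_learned[i, ], lam_true[i, ])
  }, numeric(1))
  mean(kls)
}

#' @rdname metrics
#' @export
chamfer <- function(s1, s2) {
  s1 <- truth_matrix(s1); s2 <- truth_matrix(s2)
  if (nrow(s1) < 1 || nrow(s2) < 1) stop("empty point set", call. = FALSE)
  if (ncol(s1) != ncol(s2)) stop("point sets have different dimension", call. = FALSE)
  # squared-distance matrix via ||x||^2 + ||y||^2 - 2 x.y
  D2 <- outer(rowSums(s1^2), rowSums(s2^2), `+`) - 2 * tcrossprod(s1, s2)
  D2 <- pmax(D2, 0)
  mean(apply(D2, 1, min)) + mean(apply(D2, 2, min))
}

#' @rdname metrics
#' @export
sym_log_chamfer <- function(s1, s2) {
  log((chamfer(s1, s2) + chamfer(s2, s1)) / 2)
}

#' @rdname metrics
#' @export
rmse <- function(means, zs_true) {
  if (is.data.frame(means)) {
    mcols <- grep("^m[0-9]+$", names(means), value = TRUE)
    if (length(mcols)) means <- as.matrix(means[mcols]) else means <- truth_matrix(means)
  }
  means <- as.matrix(means)
  zs_true <- truth_matrix(zs_true)
  sqrt(mean((means - zs_true)^2))
}

#' All four metrics of a filtering run
#'
#' Convenience wrapper computing RMSE, filtering log density and (when a
#' learned dynamics and attractor are supplied) the dynamics KL and symmetric
#' log Chamfer distance, returned as a one-row tibble that serializes to the
#' flat metrics JSON.
#'
#' @param fit An `evkf_fit` (or a records tibble plus `lambda`/`family`).
#' @param zs_true True latents.
#' @param true_dyn,attractor Optional: enable the dynamics metrics.
#' @param gen_steps Trajectory length generated from the learned dynamics for
#'   the Chamfer comparison.
#' @param perturb_scale Jitter scale for [dynamics_kl()].
#' @return One-row tibble.
#' @export
evaluate_fit <- function(fit, zs_true, true_dyn = NULL, attractor = NULL,
                         gen_steps = 500, perturb_scale = 0.1) {
  zs_true <- truth_matrix(zs_true)
  out <- tibble::tibble(
    rmse = rmse(fit$records, zs_true),
    log_density = filtering_log_density(fit, zs_true)
  )
  if (!is.null(true_dyn) && !is.null(attractor)) {
    out$dynamics_kl <- dynamics_kl(true_dyn, fit$dyn, attractor, perturb_scale)
    gen <- simulate_dynamics(fit$dyn, attractor[1, ], gen_steps)
    out$sym_log_chamfer <- sym_log_chamfer(gen, zs_true)
  }
  out
}
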