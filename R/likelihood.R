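#' Observation models
#'
#' Fixed-parameter observation likelihoods `p_psi(y_t | z_t)`:
#'
#' * `gaussian_likelihood(C, b, R)` — `y ~ N(C z + b, R)`.
#' * `poisson_likelihood(C, b, dt)` — spike counts
#'   `y_n ~ Poisson(dt * exp(c_n' z + b_n))`, independent across the `N`
#'   output channels; `dt` is the time-bin width in seconds.
#'
#' The readout `psi = {C, b, R, dt}` is treated as known and is not learned.
#'
#' @param C `N x L` readout matrix.
#' @param b Offset vector of length `N`.
#' @param R Observation noise covariance (SPD `N x N`).
#' @param dt Time-bin width (positive scalar).
#' @return An object of class `evkf_likelihood`.
#' @name likelihood
NULL

#' @rdname likelihood
#' @export
gaussian_likelihood <- function(C, b, R) {
  C <- as.matrix(C)
  R <- check_spd(as.matrix(R), what = "R")
  Rinv <- solve(R)
  structure(list(kind = "gaussian", C = C, b = as.numeric(b), R = R,
                 Rinv = (Rinv + t(Rinv)) / 2,
                 N = nrow(C), L = ncol(C)),
            class = c("gaussian_likelihood", "evkf_likelihood"))
}

#' @rdname likelihood
#' @export
poisson_likelihood <- function(C, b, dt) {
  C <- as.matrix(C)
  stopifnot(dt > 0)
  structure(list(kind = "poisson", C = C, b = as.numeric(b), dt = dt,
                 N = nrow(C), L = ncol(C)),
            class = c("poisson_likelihood", "evkf_likelihood"))
}

#' @export
print.evkf_likelihood <- function(x, ...) {
  cat(sprintf("<evkf_likelihood: %s, N = %d, L = %d>\n", x$kind, x$N, x$L))
  invisible(x)
}

# Log density of one observation vector given latent states (rows of z).
lik_log_density <- function(lik, y, z) {
  z <- as_state_matrix(z, lik$L)
  eta <- sweep(z %*% t(lik$C), 2, lik$b, `+`)
  if (lik$kind == "gaussian") {
    r <- sweep(eta, 2, y, `-`)
    -0.5 * rowSums((r %*% lik$Rinv) * r) -
      0.5 * (lik$N * log(2 * pi) + determinant(lik$R)$modulus[1])
  } else {
    rate <- lik$dt * exp(eta)
    rowSums(sweep(eta + log(lik$dt), 2, y, `*`) - rate) - sum(lgamma(y + 1))
  }
}

# Simulate observations for a matrix of latents (T x L rows).
lik_simulate <- function(lik, zs) {
  zs <- as_state_matrix(zs, lik$L)
  eta <- sweep(zs %*% t(lik$C), 2, lik$b, `+`)
  if (lik$kind == "gaussian") {
    eta + rnorm_mat(nrow(zs), lik$N) %*% chol(lik$R)
  } else {
    rate <- lik$dt * exp(eta)
    if (any(eta > 30)) {
      stop("Poisson rate overflow: exp argument > 30; rescale C or b", call. = FALSE)
    }
    matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
  }
}

# ---- expected log likelihood and its mean-parameter gradient ----------------
# Used by the CVI update. Each (latent family, likelihood) pair implements the
# expectation E_q[log p(y|z)] in closed form, its value, and its gradient
# expressed as a natural-parameter increment (the gradient with respect to the
# family's mean parameters).

expected_loglik <- function(lik, family, lambda, y) {
  if (inherits(family, "gaussian_family")) {
    mo <- gaussian_moments(family, lambda)
    m <- mo$m; P <- mo$P
    if (lik$kind == "gaussian") {
      r <- y - lik$b - drop(lik$C %*% m)
      -0.5 * sum(r * (lik$Rinv %*% r)) - 0.5 * sum(lik$Rinv * (lik$C %*% P %*% t(lik$C))) -
        0.5 * (lik$N * log(2 * pi) + determinant(lik$R)$modulus[1])
    } else {
      eta <- drop(lik$C %*% m) + lik$b
      quad <- rowSums((lik$C %*% P) * lik$C)
      rate <- lik$dt * exp(eta + 0.5 * quad)
      sum(y * (eta + log(lik$dt)) - rate - lgamma(y + 1))
    }
  } else if (inherits(family, "cb_family") || inherits(family, "gamma_family")) {
    if (lik$kind != "gaussian") {
      stop("only Gaussian observations are supported for CB/Gamma latents", call. = FALSE)
    }
    mv <- scalar_family_moments(family, lambda)
    r <- y - lik$b - drop(lik$C %*% mv$mean)
    CRC <- t(lik$C) %*% lik$Rinv %*% lik$C
    -0.5 * sum(r * (lik$Rinv %*% r)) - 0.5 * sum(diag(CRC) * mv$var) -
      0.5 * (lik$N * log(2 * pi) + determinant(lik$R)$modulus[1])
  } else {
    stop("unsupported latent family for expected_loglik", call. = FALSE)
  }
}

# Per-coordinate mean and variance of z under factorized scalar families.
scalar_family_moments <- function(family, lambda) {
  if (inherits(family, "cb_family")) {
    list(mean = cb_mean(lambda), var = cb_var(lambda))
  } else {
    ab <- gamma_check(family, lambda)
    list(mean = ab$alpha / ab$beta, var = ab$alpha / ab$beta^2)
  }
}

# Gradient of E_q[log p(y|z)] with respect to the family's MEAN parameters,
# returned as a flat natural-parameter increment (same layout as lambda).
expected_loglik_grad_mu <- function(lik, family, lambda, y) {
  if (inherits(family, "gaussian_family")) {
    mo <- gaussian_moments(family, lambda)
    m <- mo$m; P <- mo$P
    if (lik$kind == "gaussian") {
      g1 <- drop(t(lik$C) %*% lik$Rinv %*% (y - lik$b))
      Gp <- -0.5 * t(lik$C) %*% lik$Rinv %*% lik$C
    } else {
      eta <- drop(lik$C %*% m) + lik$b
      quad <- rowSums((lik$C %*% P) * lik$C)
      rate <- lik$dt * exp(eta + 0.5 * quad)
      Gp <- -0.5 * t(lik$C) %*% (rate * lik$C)       # grad wrt P
      gm <- drop(t(lik$C) %*% (y - rate))            # grad wrt m
      g1 <- gm - 2 * drop(Gp %*% m)
    }
    c(g1, vech((Gp + t(Gp)) / 2))
  } else if (inherits(family, "cb_family")) {
    mv <- scalar_family_moments(family, lambda)
    CRC <- t(lik$C) %*% lik$Rinv %*% lik$C
    gmean <- drop(t(lik$C) %*% lik$Rinv %*% (y - lik$b - lik$C %*% mv$mean))
    # dE/dmu_i = dE/dmean_i + dE/dvar_i * dvar/dmean; with mu = mean here,
    # chain through lambda: g = (dE/dlambda) / A''(lambda)
    gmean - 0.5 * diag(CRC) * cb_dA3(lambda) / mv$var
  } else if (inherits(family, "gamma_family")) {
    L <- family$dim_z
    ab <- gamma_check(family, lambda)
    mv <- scalar_family_moments(family, lambda)
    CRC <- t(lik$C) %*% lik$Rinv %*% lik$C
    dE_dmean <- drop(t(lik$C) %*% lik$Rinv %*% (y - lik$b - lik$C %*% mv$mean))
    dE_dvar <- -0.5 * diag(CRC)
    g <- numeric(2 * L)
    for (i in seq_len(L)) {
      a <- ab$alpha[i]; be <- ab$beta[i]
      # dE/dlambda via (mean, var) as functions of (lambda1, lambda2)
      dmean <- c(1 / be, a / be^2)                 # d(a/b)/d(l1,l2)
      dvar <- c(1 / be^2, 2 * a / be^3)            # d(a/b^2)/d(l1,l2)
      dE_dlam <- dE_dmean[i] * dmean + dE_dvar[i] * dvar
      FI <- matrix(c(trigamma(a), 1 / be, 1 / be, a / be^2), 2, 2)
      gi <- solve(FI, dE_dlam)
      g[i] <- gi[1]; g[L + i] <- gi[2]
    }
    g
  } else {
    stop("unsupported latent family for CVI", call. = FALSE)
  }
}
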