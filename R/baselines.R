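#' Classical filtering baselines
#'
#' Reference filters used both as oracles in tests and as comparison methods:
#'
#' * `kalman_filter()` — exact filter for the linear-Gaussian model
#'   `z_t ~ N(A z_{t-1}, Q)`, `y_t ~ N(C z_t + b, R)`; predict covariance
#'   `A P A' + Q`, Joseph-form update for numerical symmetry.
#' * `ekf_filter()` — extended Kalman filter: linearizes Gaussian-family
#'   dynamics about the current mean via [mean_jacobian()]; exact for linear
#'   dynamics.
#' * `bpf_filter()` — bootstrap particle filter: propagate particles through
#'   the transition, reweight by the observation density (log-domain),
#'   systematic resampling when the effective sample size falls below half the
#'   particle count.
#' * `enkf_filter()` — stochastic ensemble Kalman filter with
#'   perturbed-observation analysis (Gaussian likelihood only); no inflation
#'   or localization.
#'
#' All filters return tibbles with one row per time bin (columns `t`, `m1..mL`
#' and, where available, marginal variances `v1..vL`), matching the eVKF
#' record schema; full covariances/particles are attached as attributes where
#' noted.
#'
#' @param ys `T x N` observation matrix (or data frame; a `t` column is
#'   dropped).
#' @param A,Q,C,b,R Model matrices of the linear-Gaussian state-space model.
#' @param m0,P0 Prior mean and covariance of `z_0` (before the first predict).
#' @param dyn An `evkf_dynamics` with Gaussian family (`ekf_filter`) or any
#'   family (`bpf_filter`).
#' @param lik An `evkf_likelihood`.
#' @param n_particles,n_ens Particle / ensemble sizes (at least 2).
#' @return A tibble of filtered beliefs; `kalman_filter` and `ekf_filter`
#'   attach `"P"` (an `L x L x T` covariance array).
#' @name baselines
NULL

#' @rdname baselines
#' @export
kalman_filter <- function(ys, A, Q, C, b, R, m0, P0) {
  A <- as.matrix(A); Q <- check_spd(as.matrix(Q), what = "Q")
  C <- as.matrix(C); R <- check_spd(as.matrix(R), what = "R")
  ys <- obs_matrix(ys, nrow(C))
  L <- nrow(A); Tn <- nrow(ys)
  m <- as.numeric(m0); P <- check_spd(as.matrix(P0), what = "P0")
  ms <- matrix(NA_real_, Tn, L)
  Ps <- array(NA_real_, c(L, L, Tn))
  IL <- diag(L)
  for (t in seq_len(Tn)) {
    mp <- drop(A %*% m)
    Pp <- A %*% P %*% t(A) + Q
    S <- C %*% Pp %*% t(C) + R
    K <- t(solve(S, C %*% Pp))
    innov <- ys[t, ] - b - drop(C %*% mp)
    m <- mp + drop(K %*% innov)
    J <- IL - K %*% C
    P <- J %*% Pp %*% t(J) + K %*% R %*% t(K)   # Joseph form
    P <- (P + t(P)) / 2
    ms[t, ] <- m
    Ps[, , t] <- P
  }
  out <- belief_tibble(ms, marginal_vars(Ps, L))
  attr(out, "P") <- Ps
  out
}

marginal_vars <- function(Ps, L) {
  Tn <- dim(Ps)[3]
  out <- matrix(NA_real_, Tn, L)
  for (t in seq_len(Tn)) out[t, ] <- diag(matrix(Ps[, , t], L, L))
  out
}

belief_tibble <- function(ms, vs = NULL) {
  L <- ncol(ms)
  out <- tibble::tibble(t = seq_len(nrow(ms)))
  for (i in seq_len(L)) out[[paste0("m", i)]] <- ms[, i]
  if (!is.null(vs)) {
    vs <- as.matrix(vs)
    for (i in seq_len(L)) out[[paste0("v", i)]] <- vs[, i]
  }
  out
}

#' @rdname baselines
#' @export
ekf_filter <- function(ys, dyn, lik, m0, P0) {
  if (!inherits(dyn$family, "gaussian_family")) {
    stop("ekf_filter requires Gaussian-family dynamics", call. = FALSE)
  }
  ys <- obs_matrix(ys, lik$N)
  L <- dyn$family$dim_z; Tn <- nrow(ys)
  m <- as.numeric(m0); P <- check_spd(as.matrix(P0), what = "P0")
  ms <- matrix(NA_real_, Tn, L)
  Ps <- array(NA_real_, c(L, L, Tn))
  IL <- diag(L)
  for (t in seq_len(Tn)) {
    M <- mean_jacobian(dyn, m)
    mp <- dynamics_mean(dyn, m)
    Pp <- M %*% P %*% t(M) + dyn$Q
    if (lik$kind == "gaussian") {
      S <- lik$C %*% Pp %*% t(lik$C) + lik$R
      K <- t(solve(S, lik$C %*% Pp))
      m <- mp + drop(K %*% (ys[t, ] - lik$b - drop(lik$C %*% mp)))
      J <- IL - K %*% lik$C
      P <- J %*% Pp %*% t(J) + K %*% lik$R %*% t(K)
    } else {
      # Poisson: one Laplace-style linearized update about the predicted mean
      rate <- lik$dt * exp(drop(lik$C %*% mp) + lik$b)
      Sinv <- solve(Pp) + t(lik$C) %*% (rate * lik$C)
      P <- solve(Sinv)
      m <- mp + drop(P %*% t(lik$C) %*% (ys[t, ] - rate))
    }
    P <- (P + t(P)) / 2
    ms[t, ] <- m
    Ps[, , t] <- P
  }
  out <- belief_tibble(ms, marginal_vars(Ps, L))
  attr(out, "P") <- Ps
  out
}

# conditional-mean map of Gaussian-family dynamics
dynamics_mean <- function(dyn, z) {
  if (inherits(dyn, "linear_gaussian_dynamics")) drop(dyn$A %*% z)
  else if (inherits(dyn, "nn_gaussian_dynamics")) drop(nn_gaussian_mean(dyn, matrix(z, 1)))
  else stop("no conditional-mean map for this dynamics class", call. = FALSE)
}

#' @rdname baselines
#' @export
bpf_filter <- function(ys, dyn, lik, m0, P0, n_particles = 1000) {
  stopifnot(n_particles >= 2)
  ys <- obs_matrix(ys, lik$N)
  L <- dyn$family$dim_z; Tn <- nrow(ys)
  X <- sweep(rnorm_mat(n_particles, L) %*% chol(as.matrix(P0)), 2, as.numeric(m0), `+`)
  ms <- matrix(NA_real_, Tn, L)
  vs <- matrix(NA_real_, Tn, L)
  logw <- rep(-log(n_particles), n_particles)
  for (t in seq_len(Tn)) {
    X <- transition_propagate(dyn, X)
    logw <- logw + lik_log_density(lik, ys[t, ], X)
    mx <- max(logw)
    if (!is.finite(mx)) {
      stop(sprintf("all particle weights underflowed at step %d (max log-weight %g)",
                   t, mx), call. = FALSE)
    }
    w <- exp(logw - mx)
    w <- w / sum(w)
    ms[t, ] <- colSums(X * w)
    vs[t, ] <- colSums(X^2 * w) - ms[t, ]^2
    ess <- 1 / sum(w^2)
    if (ess < n_particles / 2) {
      X <- X[systematic_resample(w), , drop = FALSE]
      logw <- rep(-log(n_particles), n_particles)
    } else {
      logw <- log(w)
    }
  }
  belief_tibble(ms, vs)
}

systematic_resample <- function(w) {
  n <- length(w)
  u <- (stats::runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(w), left.open = TRUE) + 1L
}

#' @rdname baselines
#' @export
enkf_filter <- function(ys, dyn, lik, m0, P0, n_ens = 100) {
  stopifnot(n_ens >= 2)
  if (lik$kind != "gaussian") {
    stop("enkf_filter implements the Gaussian-observation analysis update", call. = FALSE)
  }
  ys <- obs_matrix(ys, lik$N)
  L <- dyn$family$dim_z; Tn <- nrow(ys)
  X <- sweep(rnorm_mat(n_ens, L) %*% chol(as.matrix(P0)), 2, as.numeric(m0), `+`)
  ms <- matrix(NA_real_, Tn, L)
  vs <- matrix(NA_real_, Tn, L)
  for (t in seq_len(Tn)) {
    X <- transition_propagate(dyn, X)
    Xc <- sweep(X, 2, colMeans(X))
    Pf <- crossprod(Xc) / (n_ens - 1)
    S <- lik$C %*% Pf %*% t(lik$C) + lik$R
    K <- t(solve(S, lik$C %*% Pf))
    Yp <- sweep(X %*% t(lik$C), 2, lik$b, `+`) +
      rnorm_mat(n_ens, lik$N) %*% chol(lik$R)
    X <- X + t(K %*% t(sweep(-Yp, 2, ys[t, ], `+`)))
    ms[t, ] <- colMeans(X)
    vs[t, ] <- apply(X, 2, stats::var)
  }
  belief_tibble(ms, vs)
}
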