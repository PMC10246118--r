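#' True-system dynamics classes for the simulators
#'
#' These wrap the generative systems used by the simulators as
#' `evkf_dynamics` objects, so the same objects drive simulation, filtering
#' with known dynamics, the classical baselines, and the dynamics-KL metric.
#'
#' * `crnn_dynamics(W, gamma, tau, dt, q)` — chaotic recurrent network:
#'   `z_{t+1} ~ N(z_t + (dt/tau) * (gamma W tanh(z_t) - z_t), q I)`.
#' * `vdp_dynamics(tau1, tau2, gamma, sigma, dt)` — Euler-discretized noisy
#'   Van der Pol oscillator (2-dimensional):
#'   `z1' = z1 + (dt/tau1) z2`, `z2' = z2 + (dt/tau2)(gamma (1 - z1^2) z2 - z1)`
#'   plus independent `N(0, sigma^2)` noise in each coordinate.
#' * `cb_linear_dynamics(B, c0)` — factorized continuous Bernoulli transition
#'   with natural parameters affine in the state, `lambda(z) = B (z - c0)`.
#'   With `B` a scaled rotation this produces saturating limit-cycle mean
#'   dynamics on the unit square.
#'
#' @param W `L x L` coupling matrix (the standard construction draws entries
#'   i.i.d. `N(0, 1/L)`).
#' @param gamma Gain parameter.
#' @param tau,tau1,tau2 Time constants (seconds).
#' @param dt Euler step / time-bin width (seconds).
#' @param q,sigma State-noise scale (variance `q`, standard deviation `sigma`).
#' @param B,c0 Natural-parameter map `lambda(z) = B (z - c0)`.
#' @return An `evkf_dynamics` object.
#' @name true-dynamics
NULL

#' @rdname true-dynamics
#' @export
crnn_dynamics <- function(W, gamma = 2.5, tau = 0.025, dt = 0.001, q = 1e-3) {
  W <- as.matrix(W)
  L <- nrow(W)
  Q <- diag(L) * q
  new_dynamics("crnn_dynamics", gaussian_family(L),
               W = W, gamma = gamma, tau = tau, dt = dt,
               Q = Q, Qinv = diag(L) / q, lam2h = vech(-diag(L) / (2 * q)),
               learn = FALSE)
}

crnn_mean_map <- function(dyn, z) {
  z + (dyn$dt / dyn$tau) * (dyn$gamma * tanh(z) %*% t(dyn$W) - z)
}

#' @export
eval_lambda.crnn_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, nrow(dyn$W))
  f <- crnn_mean_map(dyn, z)
  cbind(f %*% t(dyn$Qinv),
        matrix(dyn$lam2h, nrow(z), length(dyn$lam2h), byrow = TRUE))
}

#' @export
transition_propagate.crnn_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, nrow(dyn$W))
  crnn_mean_map(dyn, z) + rnorm_mat(nrow(z), ncol(z)) %*% chol(dyn$Q)
}

#' @export
mean_jacobian.crnn_dynamics <- function(dyn, z) {
  L <- nrow(dyn$W)
  r <- dyn$dt / dyn$tau
  diag(L) * (1 - r) + r * dyn$gamma * dyn$W %*% diag(1 - tanh(z)^2, L)
}

#' @export
get_theta.crnn_dynamics <- function(dyn) numeric(0)

#' @export
set_theta.crnn_dynamics <- function(dyn, theta) dyn

#' @export
grad_loss_theta.crnn_dynamics <- function(dyn, zs, resid) numeric(0)

#' @rdname true-dynamics
#' @export
vdp_dynamics <- function(tau1 = 0.1, tau2 = 0.1, gamma = 1.5, sigma = 0.05,
                         dt = 0.01) {
  Q <- diag(2) * sigma^2
  new_dynamics("vdp_dynamics", gaussian_family(2),
               tau1 = tau1, tau2 = tau2, gamma = gamma, sigma = sigma, dt = dt,
               Q = Q, Qinv = diag(2) / sigma^2,
               lam2h = vech(-diag(2) / (2 * sigma^2)), learn = FALSE)
}

vdp_mean_map <- function(dyn, z) {
  z1 <- z[, 1]; z2 <- z[, 2]
  cbind(z1 + (dyn$dt / dyn$tau1) * z2,
        z2 + (dyn$dt / dyn$tau2) * (dyn$gamma * (1 - z1^2) * z2 - z1))
}

#' @export
eval_lambda.vdp_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, 2)
  f <- vdp_mean_map(dyn, z)
  cbind(f %*% t(dyn$Qinv),
        matrix(dyn$lam2h, nrow(z), length(dyn$lam2h), byrow = TRUE))
}

#' @export
transition_propagate.vdp_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, 2)
  vdp_mean_map(dyn, z) + dyn$sigma * rnorm_mat(nrow(z), 2)
}

#' @export
mean_jacobian.vdp_dynamics <- function(dyn, z) {
  r1 <- dyn$dt / dyn$tau1
  r2 <- dyn$dt / dyn$tau2
  matrix(c(1, r2 * (-2 * dyn$gamma * z[1] * z[2] - 1),
           r1, 1 + r2 * dyn$gamma * (1 - z[1]^2)), 2, 2)
}

#' @export
get_theta.vdp_dynamics <- function(dyn) numeric(0)

#' @export
set_theta.vdp_dynamics <- function(dyn, theta) dyn

#' @export
grad_loss_theta.vdp_dynamics <- function(dyn, zs, resid) numeric(0)

#' @rdname true-dynamics
#' @export
cb_linear_dynamics <- function(B, c0 = 0.5) {
  B <- as.matrix(B)
  new_dynamics("cb_linear_dynamics", cb_family(nrow(B)),
               B = B, c0 = rep(c0, length.out = nrow(B)), learn = TRUE)
}

#' @export
eval_lambda.cb_linear_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, nrow(dyn$B))
  sweep(z, 2, dyn$c0) %*% t(dyn$B)
}

#' @export
transition_propagate.cb_linear_dynamics <- function(dyn, z) {
  cb_sample_rows(eval_lambda(dyn, z))
}

#' @export
mean_jacobian.cb_linear_dynamics <- function(dyn, z) {
  stop("mean_jacobian requires Gaussian-family dynamics", call. = FALSE)
}

#' @export
get_theta.cb_linear_dynamics <- function(dyn) as.numeric(dyn$B)

#' @export
set_theta.cb_linear_dynamics <- function(dyn, theta) {
  dyn$B[] <- theta
  dyn
}

#' @export
grad_loss_theta.cb_linear_dynamics <- function(dyn, zs, resid) {
  zs <- as_state_matrix(zs, nrow(dyn$B))
  as.numeric(tcrossprod(resid, colMeans(sweep(zs, 2, dyn$c0))))
}

# ---- simulators -------------------------------------------------------------

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

latent_tibble <- function(zs) {
  out <- tibble::tibble(t = seq_len(nrow(zs)))
  for (i in seq_len(ncol(zs))) out[[paste0("z", i)]] <- zs[, i]
  out
}

obs_tibble <- function(ys) {
  out <- tibble::tibble(t = seq_len(nrow(ys)))
  for (i in seq_len(ncol(ys))) out[[paste0("y", i)]] <- ys[, i]
  out
}

sim_output <- function(zs, ys, dyn, lik, params) {
  structure(list(latents = latent_tibble(zs), observations = obs_tibble(ys),
                 zs = zs, ys = ys, dyn = dyn, lik = lik, params = params),
            class = "evkf_sim")
}

#' @export
print.evkf_sim <- function(x, ...) {
  cat(sprintf("<evkf_sim: %s, T = %d, L = %d, N = %d (%s observations)>\n",
              x$params$system, nrow(x$zs), ncol(x$zs), ncol(x$ys), x$lik$kind))
  invisible(x)
}

#' Generate a latent trajectory from a dynamics model
#'
#' Rolls the (stochastic) transition forward from `z0`; used to compare the
#' attractor geometry of learned and true dynamics via the Chamfer metric.
#'
#' @param dyn An `evkf_dynamics`.
#' @param z0 Starting state vector.
#' @param T Number of steps.
#' @return `T x L` matrix of states.
#' @export
generate_trajectory <- function(dyn, z0, T) simulate_dynamics(dyn, z0, T)

# roll a dynamics object forward from z0 for T steps (stochastic)
simulate_dynamics <- function(dyn, z0, T) {
  L <- length(z0)
  zs <- matrix(NA_real_, T, L)
  z <- matrix(z0, 1)
  for (t in seq_len(T)) {
    z <- transition_propagate(dyn, z)
    zs[t, ] <- z
  }
  zs
}

#' Synthetic state-space data
#'
#' Simulators for the benchmark systems, each returning an `evkf_sim`: tidy
#' `latents` and `observations` tibbles, the raw `zs`/`ys` matrices, the true
#' dynamics as an `evkf_dynamics`, and the (fixed, known) observation model.
#'
#' * `simulate_lds()` — linear-Gaussian state-space model (oracle tests).
#' * `simulate_crnn()` — chaotic recurrent network latents (`gamma = 2.5`,
#'   `tau = 25 ms`, `dt = 1 ms`, `q = 1e-3`) with linear-Gaussian readout.
#' * `simulate_vdp()` — noisy Van der Pol oscillator with Poisson spike-count
#'   observations `y ~ Poisson(dt * exp(C z + b))`; `C` entries are i.i.d.
#'   `N(0, 0.25)` and `b` is calibrated so the mean count per bin matches
#'   `target_rate` (0.1 by default).
#' * `simulate_cb()` — factorized continuous Bernoulli latents on the unit
#'   square with saturating rotational mean dynamics and Gaussian readout
#'   `y_n ~ N(c_n' z, r^2)`.
#'
#' @param L,N,T Latent dimension, observation channels, stream length.
#' @param A,Q,C,b,R Linear-Gaussian model matrices (`simulate_lds`).
#' @param m0,P0 Initial-state distribution.
#' @param gamma,tau,dt,q CRNN parameters (see [crnn_dynamics()]).
#' @param obs_noise Gaussian observation noise variance (CRNN, CB).
#' @param tau1,tau2,sigma Van der Pol parameters (see [vdp_dynamics()]).
#' @param target_rate Mean spike count per bin used to calibrate `b`.
#' @param kappa,angle CB fixture: `B = kappa * rotation(angle)`.
#' @param seed Optional seed; the run is reproducible given (seed, arguments).
#' @return An object of class `evkf_sim`.
#' @name simulators
NULL

#' @rdname simulators
#' @export
simulate_lds <- function(L = 1, N = 1, T = 100,
                         A = matrix(0.9), Q = matrix(0.1),
                         C = matrix(1), b = 0, R = matrix(0.5),
                         m0 = numeric(L), P0 = diag(L), seed = NULL) {
  with_seed(seed, {
    dyn <- linear_gaussian_dynamics(as.matrix(A), as.matrix(Q))
    lik <- gaussian_likelihood(C, b, R)
    z0 <- drop(m0 + t(chol(as.matrix(P0))) %*% stats::rnorm(L))
    zs <- simulate_dynamics(dyn, z0, T)
    ys <- lik_simulate(lik, zs)
    sim_output(zs, ys, dyn, lik,
               list(system = "lds", A = as.matrix(A), Q = as.matrix(Q),
                    m0 = m0, P0 = as.matrix(P0), seed = seed))
  })
}

#' @rdname simulators
#' @export
simulate_crnn <- function(L = 2, N = 10, T = 250, gamma = 2.5, tau = 0.025,
                          dt = 0.001, q = 1e-3, obs_noise = 0.1, seed = NULL) {
  with_seed(seed, {
    W <- matrix(stats::rnorm(L * L, sd = 1 / sqrt(L)), L, L)
    dyn <- crnn_dynamics(W, gamma = gamma, tau = tau, dt = dt, q = q)
    C <- matrix(stats::rnorm(N * L, sd = 1 / sqrt(L)), N, L)
    lik <- gaussian_likelihood(C, numeric(N), diag(N) * obs_noise)
    zs <- simulate_dynamics(dyn, stats::rnorm(L, sd = 0.5), T)
    ys <- lik_simulate(lik, zs)
    sim_output(zs, ys, dyn, lik,
               list(system = "crnn", W = W, gamma = gamma, tau = tau, dt = dt,
                    q = q, obs_noise = obs_noise, seed = seed))
  })
}

#' @rdname simulators
#' @export
simulate_vdp <- function(T = 1000, N = 50, tau1 = 0.1, tau2 = 0.1,
                         gamma = 1.5, sigma = 0.05, dt = 0.01,
                         target_rate = 0.1, seed = NULL) {
  with_seed(seed, {
    dyn <- vdp_dynamics(tau1, tau2, gamma, sigma, dt)
    zs <- simulate_dynamics(dyn, c(1, 0), T)
    C <- matrix(stats::rnorm(N * 2, sd = 0.5), N, 2)
    # calibrate offsets so each channel's mean count per bin is target_rate
    b <- log(target_rate / dt) - log(colMeans(exp(zs %*% t(C))))
    lik <- poisson_likelihood(C, b, dt)
    ys <- lik_simulate(lik, zs)
    sim_output(zs, ys, dyn, lik,
               list(system = "vdp", tau1 = tau1, tau2 = tau2, gamma = gamma,
                    sigma = sigma, dt = dt, target_rate = target_rate,
                    seed = seed))
  })
}

#' @rdname simulators
#' @export
simulate_cb <- function(T = 1000, N = 10, L = 2, kappa = 16, angle = pi / 4,
                        obs_noise = 0.05, seed = NULL) {
  with_seed(seed, {
    Rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
    B <- kappa * Rot
    dyn <- cb_linear_dynamics(B)
    C <- matrix(stats::rnorm(N * L, sd = 1), N, L)
    lik <- gaussian_likelihood(C, numeric(N), diag(N) * obs_noise)
    zs <- simulate_dynamics(dyn, stats::runif(L), T)
    ys <- lik_simulate(lik, zs)
    sim_output(zs, ys, dyn, lik,
               list(system = "cb", B = B, kappa = kappa, angle = angle,
                    obs_noise = obs_noise, seed = seed))
  })
}

#' Noise-free attractor samples of a dynamics model
#'
#' Iterates the deterministic mean map of a dynamics object from `z0`,
#' discards a burn-in, and returns the last `n` states — points on (or near)
#' the system's attractor, used by [dynamics_kl()] and the Chamfer metric.
#'
#' @param dyn An `evkf_dynamics` with a conditional-mean map (Gaussian
#'   families) or a CB dynamics (mean map `A'(lambda(z))`).
#' @param z0 Starting state.
#' @param n Number of points returned.
#' @param burn Burn-in steps discarded.
#' @return `n x L` matrix.
#' @export
attractor_points <- function(dyn, z0, n = 500, burn = 1500) {
  L <- dyn$family$dim_z
  z <- matrix(z0, 1)
  out <- matrix(NA_real_, n, L)
  total <- burn + n
  for (t in seq_len(total)) {
    z <- deterministic_step(dyn, z)
    if (t > burn) out[t - burn, ] <- z
  }
  out
}

deterministic_step <- function(dyn, z) {
  if (inherits(dyn, "vdp_dynamics")) vdp_mean_map(dyn, z)
  else if (inherits(dyn, "crnn_dynamics")) crnn_mean_map(dyn, z)
  else if (inherits(dyn, "linear_gaussian_dynamics")) z %*% t(dyn$A)
  else if (inherits(dyn, "nn_gaussian_dynamics")) nn_gaussian_mean(dyn, z)
  else if (inherits(dyn$family, "cb_family")) {
    lam <- eval_lambda(dyn, z)
    matrix(cb_mean(as.numeric(lam)), 1)
  } else {
    stop("no deterministic mean map for this dynamics class", call. = FALSE)
  }
}
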