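#' Conditional exponential-family dynamics models
#'
#' A dynamics object represents the conditional transition
#' `p_theta(z_t | z_{t-1})` of a state-space model through the natural-parameter
#' map `lambda_theta(z_{t-1})`: for every previous state it returns a valid
#' natural parameter of the transition family. Shipped model classes:
#'
#' * `linear_gaussian_dynamics(A, Q)` — `z_t | z_{t-1} ~ N(A z_{t-1}, Q)`,
#'   i.e. `lambda_theta(z) = (Q^{-1} A z, -Q^{-1}/2)`. Trainable parameter:
#'   `A` (Q is held fixed).
#' * `nn_gaussian_dynamics(L, hidden, Q, ...)` — `N(f_theta(z), Q)` with
#'   `f_theta` a tanh multilayer perceptron; trainable parameter: the network
#'   weights (Q fixed).
#' * `nn_cb_dynamics(L, hidden, ...)` — factorized continuous Bernoulli
#'   transition whose natural parameters are the (unconstrained) network
#'   outputs.
#' * `nn_gamma_dynamics(L, hidden, ...)` — factorized Gamma transition; the
#'   network outputs pass through softplus links so the naturals satisfy
#'   `lambda1 > -1`, `lambda2 < 0`.
#' * `constant_dynamics(family, lambda0)` — a state-independent transition
#'   with one free natural-parameter vector (a "table lookup" map), mainly
#'   useful for checking the dynamics-learning fixed point.
#'
#' @param A Transition matrix (`L x L`).
#' @param Q State-noise covariance (SPD, `L x L`).
#' @param L Latent dimension.
#' @param hidden Integer vector of hidden-layer widths.
#' @param init_scale Weight-initialisation scale.
#' @param seed Optional seed for weight initialisation.
#' @param learn Logical: expose parameters to the learning step?
#' @param family,lambda0 Family and natural vector for `constant_dynamics`.
#' @return An object of class `evkf_dynamics`.
#' @name dynamics
NULL

new_dynamics <- function(class, family, ...) {
  structure(c(list(family = family), list(...)),
            class = c(class, "evkf_dynamics"))
}

#' @rdname dynamics
#' @export
linear_gaussian_dynamics <- function(A, Q, learn = TRUE) {
  A <- as.matrix(A)
  Q <- check_spd(as.matrix(Q), what = "Q")
  L <- nrow(A)
  Qinv <- solve(Q)
  Qinv <- (Qinv + t(Qinv)) / 2
  new_dynamics("linear_gaussian_dynamics", gaussian_family(L),
               A = A, Q = Q, Qinv = Qinv, lam2h = vech(-Qinv / 2),
               learn = learn)
}

#' @rdname dynamics
#' @export
nn_gaussian_dynamics <- function(L, hidden = c(64, 64), Q = diag(L) * 0.01,
                                 init_scale = 1, seed = NULL,
                                 residual = FALSE) {
  Q <- check_spd(as.matrix(Q), what = "Q")
  Qinv <- solve(Q)
  Qinv <- (Qinv + t(Qinv)) / 2
  net <- mlp_new(c(L, hidden, L), init_scale = init_scale, seed = seed)
  new_dynamics("nn_gaussian_dynamics", gaussian_family(L),
               net = net, Q = Q, Qinv = Qinv, lam2h = vech(-Qinv / 2),
               residual = isTRUE(residual), learn = TRUE)
}

# conditional mean of the NN-Gaussian map; residual mode models the drift,
# f(z) = z + net(z), the natural parameterization for Euler-discretized flows
nn_gaussian_mean <- function(dyn, z) {
  f <- mlp_forward(dyn$net, z)$out
  if (isTRUE(dyn$residual)) z + f else f
}

#' @rdname dynamics
#' @export
nn_cb_dynamics <- function(L, hidden = c(64, 64), init_scale = 1, seed = NULL) {
  net <- mlp_new(c(L, hidden, L), init_scale = init_scale, seed = seed)
  new_dynamics("nn_cb_dynamics", cb_family(L), net = net, learn = TRUE)
}

#' @rdname dynamics
#' @export
nn_gamma_dynamics <- function(L, hidden = c(64, 64), init_scale = 1, seed = NULL) {
  net <- mlp_new(c(L, hidden, 2 * L), init_scale = init_scale, seed = seed)
  new_dynamics("nn_gamma_dynamics", gamma_family(L), net = net, learn = TRUE)
}

#' @rdname dynamics
#' @export
constant_dynamics <- function(family, lambda0) {
  check_lambda(family, lambda0)
  new_dynamics("constant_dynamics", family, lambda0 = lambda0, learn = TRUE)
}

#' @export
print.evkf_dynamics <- function(x, ...) {
  cat(sprintf("<evkf_dynamics: %s over %s family, dim_z = %d, %d parameters>\n",
              class(x)[1], x$family$name, x$family$dim_z, length(get_theta(x))))
  invisible(x)
}

# ---- generic operations -----------------------------------------------------

#' Evaluate, sample and differentiate a dynamics model
#'
#' `eval_lambda` maps a batch of previous states (rows of `z`) to the natural
#' parameters of the next-state conditional. `transition_propagate` draws one
#' next state per row. `mean_jacobian` returns the Jacobian of the conditional
#' mean map at a point (Gaussian-family dynamics only; used by the EKF-like
#' variance correction). `get_theta`/`set_theta` expose the flat trainable
#' parameter vector.
#'
#' @param dyn An `evkf_dynamics` object.
#' @param z Matrix (`n x L`) of states, or a single state vector.
#' @param theta Flat numeric parameter vector.
#' @return `eval_lambda`: `n x dim_lambda` matrix. `transition_propagate`:
#'   `n x L` matrix. `mean_jacobian`: `L x L` matrix.
#' @name dynamics-ops
NULL

#' @rdname dynamics-ops
#' @export
eval_lambda <- function(dyn, z) UseMethod("eval_lambda")

#' @rdname dynamics-ops
#' @export
transition_propagate <- function(dyn, z) UseMethod("transition_propagate")

#' @rdname dynamics-ops
#' @export
mean_jacobian <- function(dyn, z) UseMethod("mean_jacobian")

#' @rdname dynamics-ops
#' @export
get_theta <- function(dyn) UseMethod("get_theta")

#' @rdname dynamics-ops
#' @export
set_theta <- function(dyn, theta) UseMethod("set_theta")

# Exact E_q[lambda_theta(z)] where available; NULL otherwise.
expected_lambda_exact <- function(dyn, lambda_prev) UseMethod("expected_lambda_exact")

#' @export
expected_lambda_exact.default <- function(dyn, lambda_prev) NULL

# Gradient of 1/2 ||lambda_bar_theta - lambda_star||^2 wrt theta, given the
# sample batch zs used to form lambda_bar_theta and the residual
# resid = lambda_bar_theta - lambda_star.
grad_loss_theta <- function(dyn, zs, resid) UseMethod("grad_loss_theta")

as_state_matrix <- function(z, L) {
  if (is.null(dim(z))) matrix(z, ncol = L, byrow = TRUE) else as.matrix(z)
}

# ---- linear Gaussian --------------------------------------------------------

#' @export
eval_lambda.linear_gaussian_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, ncol(dyn$A))
  lam1 <- z %*% t(dyn$Qinv %*% dyn$A)
  cbind(lam1, matrix(dyn$lam2h, nrow(z), length(dyn$lam2h), byrow = TRUE))
}

#' @export
transition_propagate.linear_gaussian_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, ncol(dyn$A))
  z %*% t(dyn$A) + rnorm_mat(nrow(z), ncol(dyn$A)) %*% chol(dyn$Q)
}

#' @export
mean_jacobian.linear_gaussian_dynamics <- function(dyn, z) dyn$A

#' @export
get_theta.linear_gaussian_dynamics <- function(dyn) as.numeric(dyn$A)

#' @export
set_theta.linear_gaussian_dynamics <- function(dyn, theta) {
  dyn$A[] <- theta
  dyn
}

#' @export
expected_lambda_exact.linear_gaussian_dynamics <- function(dyn, lambda_prev) {
  mo <- gaussian_moments(dyn$family, lambda_prev)
  c(dyn$Qinv %*% dyn$A %*% mo$m, dyn$lam2h)
}

#' @export
grad_loss_theta.linear_gaussian_dynamics <- function(dyn, zs, resid) {
  L <- ncol(dyn$A)
  r1 <- resid[seq_len(L)]
  zbar <- colMeans(as_state_matrix(zs, L))
  as.numeric(tcrossprod(t(dyn$Qinv) %*% r1, zbar))
}

# ---- NN Gaussian ------------------------------------------------------------

#' @export
eval_lambda.nn_gaussian_dynamics <- function(dyn, z) {
  L <- dyn$family$dim_z
  z <- as_state_matrix(z, L)
  cbind(nn_gaussian_mean(dyn, z) %*% t(dyn$Qinv),
        matrix(dyn$lam2h, nrow(z), length(dyn$lam2h), byrow = TRUE))
}

#' @export
transition_propagate.nn_gaussian_dynamics <- function(dyn, z) {
  L <- dyn$family$dim_z
  z <- as_state_matrix(z, L)
  nn_gaussian_mean(dyn, z) + rnorm_mat(nrow(z), L) %*% chol(dyn$Q)
}

#' @export
mean_jacobian.nn_gaussian_dynamics <- function(dyn, z) {
  J <- mlp_jacobian(dyn$net, z)
  if (isTRUE(dyn$residual)) diag(dyn$family$dim_z) + J else J
}

#' @export
get_theta.nn_gaussian_dynamics <- function(dyn) mlp_flatten(dyn$net)

#' @export
set_theta.nn_gaussian_dynamics <- function(dyn, theta) {
  dyn$net <- mlp_unflatten(dyn$net, theta)
  dyn
}

#' @export
grad_loss_theta.nn_gaussian_dynamics <- function(dyn, zs, resid) {
  L <- dyn$family$dim_z
  zs <- as_state_matrix(zs, L)
  n <- nrow(zs)
  cache <- mlp_forward(dyn$net, zs)
  # upstream gradient on f(z_i): Qinv^T r1 / n, identical across samples
  up <- drop(t(dyn$Qinv) %*% resid[seq_len(L)]) / n
  G <- matrix(up, n, L, byrow = TRUE)
  mlp_grad_flatten(mlp_backward(dyn$net, cache, G))
}

# ---- NN continuous Bernoulli ------------------------------------------------

#' @export
eval_lambda.nn_cb_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, dyn$family$dim_z)
  mlp_forward(dyn$net, z)$out
}

#' @export
transition_propagate.nn_cb_dynamics <- function(dyn, z) {
  lam <- eval_lambda(dyn, z)
  cb_sample_rows(lam)
}

#' @export
mean_jacobian.nn_cb_dynamics <- function(dyn, z) {
  stop("mean_jacobian requires Gaussian-family dynamics", call. = FALSE)
}

#' @export
get_theta.nn_cb_dynamics <- function(dyn) mlp_flatten(dyn$net)

#' @export
set_theta.nn_cb_dynamics <- function(dyn, theta) {
  dyn$net <- mlp_unflatten(dyn$net, theta)
  dyn
}

#' @export
grad_loss_theta.nn_cb_dynamics <- function(dyn, zs, resid) {
  zs <- as_state_matrix(zs, dyn$family$dim_z)
  n <- nrow(zs)
  cache <- mlp_forward(dyn$net, zs)
  G <- matrix(resid / n, n, length(resid), byrow = TRUE)
  mlp_grad_flatten(mlp_backward(dyn$net, cache, G))
}

# One CB draw per row of a natural-parameter matrix (n x L).
cb_sample_rows <- function(lam) {
  u <- matrix(stats::runif(length(lam)), nrow(lam), ncol(lam))
  z <- u
  big <- abs(lam) >= 1e-4
  z[big] <- log1p(u[big] * expm1(lam[big])) / lam[big]
  z
}

# ---- NN Gamma ---------------------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' @export
eval_lambda.nn_gamma_dynamics <- function(dyn, z) {
  L <- dyn$family$dim_z
  z <- as_state_matrix(z, L)
  o <- mlp_forward(dyn$net, z)$out
  cbind(softplus(o[, seq_len(L), drop = FALSE]) - 1,
        -softplus(o[, L + seq_len(L), drop = FALSE]) - 1e-6)
}

#' @export
transition_propagate.nn_gamma_dynamics <- function(dyn, z) {
  lam <- eval_lambda(dyn, z)
  L <- dyn$family$dim_z
  alpha <- lam[, seq_len(L), drop = FALSE] + 1
  beta <- -lam[, L + seq_len(L), drop = FALSE]
  matrix(stats::rgamma(length(alpha), shape = alpha, rate = beta),
         nrow(alpha), ncol(alpha))
}

#' @export
mean_jacobian.nn_gamma_dynamics <- function(dyn, z) {
  stop("mean_jacobian requires Gaussian-family dynamics", call. = FALSE)
}

#' @export
get_theta.nn_gamma_dynamics <- function(dyn) mlp_flatten(dyn$net)

#' @export
set_theta.nn_gamma_dynamics <- function(dyn, theta) {
  dyn$net <- mlp_unflatten(dyn$net, theta)
  dyn
}

#' @export
grad_loss_theta.nn_gamma_dynamics <- function(dyn, zs, resid) {
  L <- dyn$family$dim_z
  zs <- as_state_matrix(zs, L)
  n <- nrow(zs)
  cache <- mlp_forward(dyn$net, zs)
  o <- cache$out
  # chain through the softplus links: dlam1/do1 = sigmoid(o1), dlam2/do2 = -sigmoid(o2)
  link <- cbind(stats::plogis(o[, seq_len(L), drop = FALSE]),
                -stats::plogis(o[, L + seq_len(L), drop = FALSE]))
  G <- sweep(link, 2, resid / n, `*`)
  mlp_grad_flatten(mlp_backward(dyn$net, cache, G))
}

# ---- constant ("table lookup") ----------------------------------------------

#' @export
eval_lambda.constant_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, dyn$family$dim_z)
  matrix(dyn$lambda0, nrow(z), length(dyn$lambda0), byrow = TRUE)
}

#' @export
transition_propagate.constant_dynamics <- function(dyn, z) {
  z <- as_state_matrix(z, dyn$family$dim_z)
  ef_sample(dyn$family, dyn$lambda0, nrow(z))
}

#' @export
mean_jacobian.constant_dynamics <- function(dyn, z) {
  if (!inherits(dyn$family, "gaussian_family")) {
    stop("mean_jacobian requires Gaussian-family dynamics", call. = FALSE)
  }
  matrix(0, dyn$family$dim_z, dyn$family$dim_z)
}

#' @export
get_theta.constant_dynamics <- function(dyn) dyn$lambda0

#' @export
set_theta.constant_dynamics <- function(dyn, theta) {
  dyn$lambda0 <- theta
  dyn
}

#' @export
expected_lambda_exact.constant_dynamics <- function(dyn, lambda_prev) dyn$lambda0

#' @export
grad_loss_theta.constant_dynamics <- function(dyn, zs, resid) resid
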