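# Minimal multilayer perceptron with hand-written backprop. No autodiff
# framework ships with this R installation, so gradients and Jacobians are
# analytic; tests check them against central finite differences.

mlp_new <- function(dims, init_scale = 1, seed = NULL) {
  # dims: c(in, hidden..., out); tanh hidden units, linear output head
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_lay <- length(dims) - 1
  W <- vector("list", n_lay)
  b <- vector("list", n_lay)
  for (k in seq_len(n_lay)) {
    W[[k]] <- matrix(stats::rnorm(dims[k] * dims[k + 1], sd = init_scale / sqrt(dims[k])),
                     dims[k], dims[k + 1])
    b[[k]] <- numeric(dims[k + 1])
  }
  structure(list(W = W, b = b, dims = dims), class = "evkf_mlp")
}

# Forward pass on a batch X (n x in). Returns output and cached activations.
mlp_forward <- function(net, X) {
  n_lay <- length(net$W)
  acts <- vector("list", n_lay + 1)
  acts[[1]] <- X
  H <- X
  for (k in seq_len(n_lay)) {
    Z <- sweep(H %*% net$W[[k]], 2, net$b[[k]], `+`)
    H <- if (k < n_lay) tanh(Z) else Z
    acts[[k + 1]] <- H
  }
  list(out = H, acts = acts)
}

# Backprop: G is the gradient of the loss wrt the output (n x out).
# Returns parameter gradients and the gradient wrt the input batch.
mlp_backward <- function(net, cache, G) {
  n_lay <- length(net$W)
  gW <- vector("list", n_lay)
  gb <- vector("list", n_lay)
  D <- G
  for (k in n_lay:1) {
    if (k < n_lay) D <- D * (1 - cache$acts[[k + 1]]^2)  # tanh'
    gW[[k]] <- crossprod(cache$acts[[k]], D)
    gb[[k]] <- colSums(D)
    D <- D %*% t(net$W[[k]])
  }
  list(gW = gW, gb = gb, gX = D)
}

# Jacobian of the network output wrt a single input point z (out x in).
mlp_jacobian <- function(net, z) {
  cache <- mlp_forward(net, matrix(z, nrow = 1))
  n_lay <- length(net$W)
  J <- t(net$W[[n_lay]])                       # out x d_{last hidden}
  if (n_lay > 1) {
    for (k in (n_lay - 1):1) {
      dk <- 1 - cache$acts[[k + 1]][1, ]^2
      J <- (J * rep(dk, each = nrow(J))) %*% t(net$W[[k]])
    }
  }
  J
}

mlp_flatten <- function(net) {
  unlist(c(lapply(net$W, as.numeric), lapply(net$b, as.numeric)))
}

mlp_unflatten <- function(net, theta) {
  pos <- 0
  for (k in seq_along(net$W)) {
    nk <- length(net$W[[k]])
    net$W[[k]][] <- theta[pos + seq_len(nk)]
    pos <- pos + nk
  }
  for (k in seq_along(net$b)) {
    nk <- length(net$b[[k]])
    net$b[[k]][] <- theta[pos + seq_len(nk)]
    pos <- pos + nk
  }
  net
}

mlp_grad_flatten <- function(g) unlist(c(lapply(g$gW, as.numeric), lapply(g$gb, as.numeric)))

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(n_par) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, grad, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(state = state, delta = -lr * mhat / (sqrt(vhat) + state$eps))
}

sgd_init <- function(n_par) list(t = 0L)

sgd_step <- function(state, grad, lr) {
  state$t <- state$t + 1L
  list(state = state, delta = -lr * grad)
}

optimizer_init <- function(kind, n_par) {
  switch(kind, adam = adam_init(n_par), sgd = sgd_init(n_par),
         stop("unknown optimizer: ", kind, call. = FALSE))
}

optimizer_step <- function(kind, state, grad, lr) {
  switch(kind, adam = adam_step(state, grad, lr), sgd = sgd_step(state, grad, lr))
}
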