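# Factorized scalar families: continuous Bernoulli, Gamma, Bernoulli.
# Each coordinate is an independent one-dimensional family; flat parameter
# vectors concatenate per-coordinate blocks.

# ---- continuous Bernoulli ---------------------------------------------------
# Density on [0,1]: exp(lambda * z - A(lambda)), A(lambda) = log((e^lambda - 1)/lambda).
# Series expansions take over near lambda = 0 where the closed forms are 0/0.

cb_logA <- function(lam) {
  out <- numeric(length(lam))
  small <- abs(lam) < 1e-4
  out[small] <- lam[small] / 2 + lam[small]^2 / 24
  lp <- lam[!small & lam > 0]
  ln <- lam[!small & lam < 0]
  out[!small & lam > 0] <- lp + log(-expm1(-lp)) - log(lp)
  out[!small & lam < 0] <- log(-expm1(ln)) - log(-ln)
  out
}

cb_mean <- function(lam) {
  out <- numeric(length(lam))
  small <- abs(lam) < 1e-4
  ls <- lam[small]
  out[small] <- 0.5 + ls / 12 - ls^3 / 720
  lb <- lam[!small]
  out[!small] <- 1 / (-expm1(-lb)) - 1 / lb
  out
}

cb_var <- function(lam) {
  out <- numeric(length(lam))
  small <- abs(lam) < 1e-2
  ls <- lam[small]
  out[small] <- 1 / 12 - ls^2 / 240 + ls^4 / 6048
  lb <- lam[!small]
  out[!small] <- 1 / lb^2 - 0.25 / sinh(lb / 2)^2
  out
}

# third derivative of A
cb_dA3 <- function(lam) {
  out <- numeric(length(lam))
  small <- abs(lam) < 1e-2
  ls <- lam[small]
  out[small] <- -ls / 120 + ls^3 / 1512
  lb <- lam[!small]
  out[!small] <- -2 / lb^3 + cosh(lb / 2) / (4 * sinh(lb / 2)^3)
  out
}

# Inverse of the mean map, per coordinate; monotone root-finding to 1e-10,
# then one Newton polish.
cb_natural_of_mean <- function(mu) {
  if (any(mu <= 0 | mu >= 1)) {
    stop("continuous Bernoulli mean must lie strictly inside (0,1)", call. = FALSE)
  }
  vapply(mu, function(m) {
    if (abs(m - 0.5) < 1e-12) return(0)
    b <- 10 / min(m, 1 - m) + 10
    r <- stats::uniroot(function(l) cb_mean(l) - m, c(-b, b), tol = 1e-12)$root
    r - (cb_mean(r) - m) / cb_var(r)
  }, numeric(1))
}

#' @export
log_h.cb_family <- function(family) 0

#' @export
log_partition.cb_family <- function(family, lambda) {
  check_lambda(family, lambda)
  sum(cb_logA(lambda))
}

#' @export
natural_to_mean.cb_family <- function(family, lambda) {
  check_lambda(family, lambda)
  cb_mean(lambda)
}

#' @export
mean_to_natural.cb_family <- function(family, mu) cb_natural_of_mean(mu)

#' @export
ef_sample.cb_family <- function(family, lambda, n = 1) {
  check_lambda(family, lambda)
  L <- family$dim_z
  u <- matrix(stats::runif(n * L), n, L)
  lam <- matrix(lambda, n, L, byrow = TRUE)
  z <- u
  big <- abs(lam) >= 1e-4
  # inverse CDF: F^{-1}(u) = log(1 + u (e^lambda - 1)) / lambda
  z[big] <- log1p(u[big] * expm1(lam[big])) / lam[big]
  z
}

#' @export
ef_suffstat.cb_family <- function(family, z) z

#' @export
ef_fisher.cb_family <- function(family, lambda) diag(cb_var(lambda), family$dim_z)

# ---- Gamma ------------------------------------------------------------------
# t(z) = (log z, z); lambda = (alpha - 1, -beta) stored as two blocks of
# length L. Valid iff lambda1 > -1, lambda2 < 0.

gamma_check <- function(family, lambda) {
  check_lambda(family, lambda)
  L <- family$dim_z
  if (any(lambda[seq_len(L)] <= -1) || any(lambda[-seq_len(L)] >= 0)) {
    stop("Gamma naturals require lambda1 > -1 and lambda2 < 0", call. = FALSE)
  }
  list(alpha = lambda[seq_len(L)] + 1, beta = -lambda[-seq_len(L)])
}

#' @export
log_h.gamma_family <- function(family) 0

#' @export
log_partition.gamma_family <- function(family, lambda) {
  ab <- gamma_check(family, lambda)
  sum(lgamma(ab$alpha) - ab$alpha * log(ab$beta))
}

#' @export
natural_to_mean.gamma_family <- function(family, lambda) {
  ab <- gamma_check(family, lambda)
  c(digamma(ab$alpha) - log(ab$beta), ab$alpha / ab$beta)
}

#' @export
mean_to_natural.gamma_family <- function(family, mu) {
  L <- family$dim_z
  elog <- mu[seq_len(L)]
  ez <- mu[-seq_len(L)]
  if (any(ez <= 0)) stop("Gamma mean E[z] must be positive", call. = FALSE)
  s <- log(ez) - elog          # log(alpha) - digamma(alpha) > 0 by Jensen
  if (any(s <= 0)) stop("invalid Gamma moments: log E[z] <= E[log z]", call. = FALSE)
  alpha <- vapply(s, function(si) {
    f <- function(la) la - digamma(exp(la)) - si   # root in log(alpha)
    r <- stats::uniroot(f, c(-30, 30), tol = 1e-13, extendInt = "downX")$root
    a <- exp(r)
    # Newton polish on g(a) = log a - digamma(a) - s
    a - (log(a) - digamma(a) - si) / (1 / a - trigamma(a))
  }, numeric(1))
  beta <- alpha / ez
  c(alpha - 1, -beta)
}

#' @export
ef_sample.gamma_family <- function(family, lambda, n = 1) {
  ab <- gamma_check(family, lambda)
  L <- family$dim_z
  matrix(stats::rgamma(n * L, shape = rep(ab$alpha, each = n),
                       rate = rep(ab$beta, each = n)), n, L)
}

#' @export
ef_suffstat.gamma_family <- function(family, z) {
  if (any(z <= 0)) stop("Gamma support is the positive reals", call. = FALSE)
  cbind(log(z), z)
}

#' @export
ef_fisher.gamma_family <- function(family, lambda) {
  ab <- gamma_check(family, lambda)
  L <- family$dim_z
  FI <- matrix(0, 2 * L, 2 * L)
  for (i in seq_len(L)) {
    # per-coordinate Hessian of A wrt (lambda1, lambda2)
    FI[i, i] <- trigamma(ab$alpha[i])
    FI[i, L + i] <- FI[L + i, i] <- 1 / ab$beta[i]
    FI[L + i, L + i] <- ab$alpha[i] / ab$beta[i]^2
  }
  FI
}

# ---- Bernoulli --------------------------------------------------------------

#' @export
log_h.bernoulli_family <- function(family) 0

#' @export
log_partition.bernoulli_family <- function(family, lambda) {
  check_lambda(family, lambda)
  # log(1 + e^lambda), stable
  sum(ifelse(lambda > 0, lambda + log1p(exp(-lambda)), log1p(exp(lambda))))
}

#' @export
natural_to_mean.bernoulli_family <- function(family, lambda) {
  check_lambda(family, lambda)
  stats::plogis(lambda)
}

#' @export
mean_to_natural.bernoulli_family <- function(family, mu) {
  if (any(mu <= 0 | mu >= 1)) stop("Bernoulli mean must be in (0,1)", call. = FALSE)
  stats::qlogis(mu)
}

#' @export
ef_sample.bernoulli_family <- function(family, lambda, n = 1) {
  check_lambda(family, lambda)
  L <- family$dim_z
  p <- stats::plogis(lambda)
  matrix(stats::rbinom(n * L, 1, rep(p, each = n)), n, L)
}

#' @export
ef_suffstat.bernoulli_family <- function(family, z) z

#' @export
ef_fisher.bernoulli_family <- function(family, lambda) {
  p <- stats::plogis(lambda)
  diag(p * (1 - p), family$dim_z)
}
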