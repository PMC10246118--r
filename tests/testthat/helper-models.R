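# Shared fixtures built in code: random valid parameters per family, random
# stable linear-Gaussian systems, and a central-finite-difference gradient.

random_spd <- function(L, scale = 1) {
  M <- matrix(rnorm(L * L), L, L)
  crossprod(M) / L * scale + diag(L) * 0.1 * scale
}

random_lambda <- function(family) {
  L <- family$dim_z
  if (inherits(family, "gaussian_family")) {
    gaussian_natural(rnorm(L), random_spd(L))
  } else if (inherits(family, "cb_family")) {
    rnorm(L, sd = 2)
  } else if (inherits(family, "gamma_family")) {
    c(exp(rnorm(L, sd = 0.5)) - 0.5, -exp(rnorm(L, sd = 0.5)))
  } else if (inherits(family, "bernoulli_family")) {
    rnorm(L, sd = 2)
  } else stop("unknown family")
}

all_families <- function(L = 2) {
  list(gaussian = gaussian_family(L), cb = cb_family(L),
       gamma = gamma_family(L), bernoulli = bernoulli_family(L))
}

# random stable linear-Gaussian state-space model
random_lds <- function(L = 2, N = 2, spectral_radius = 0.9) {
  A <- matrix(rnorm(L * L), L, L)
  A <- A / max(Mod(eigen(A, only.values = TRUE)$values)) * spectral_radius
  list(A = A, Q = random_spd(L, 0.3), C = matrix(rnorm(N * L), N, L),
       b = rnorm(N), R = random_spd(N, 0.5),
       m0 = rnorm(L, sd = 0.3), P0 = diag(L) * 0.5)
}

# central finite differences of a scalar function
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
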