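# Exponential-family algebra: log-partition values, natural/mean duality,
# round trips, sampling, KL and entropy, for all shipped families.

test_that("log-partition matches known values", {
  expect_equal(log_partition(gaussian_family(1), c(0, -0.5)), 0)
  expect_equal(log_partition(cb_family(1), 0), 0)
  # Gamma(2, 1): A = log Gamma(2) - 2 log 1 = 0; quadrature oracle
  expect_equal(log_partition(gamma_family(1), c(1, -1)), 0)
  quad <- integrate(function(z) z * exp(-z), 0, Inf)$value
  expect_equal(exp(log_partition(gamma_family(1), c(1, -1))), quad, tolerance = 1e-8)
  # CB at lambda = 2 against quadrature of int_0^1 e^{2z} dz
  quad_cb <- integrate(function(z) exp(2 * z), 0, 1)$value
  expect_equal(log_partition(cb_family(1), 2), log(quad_cb), tolerance = 1e-8)
})

test_that("natural_to_mean equals the gradient of the log-partition", {
  set.seed(11)
  for (fam in all_families(2)) {
    for (rep in 1:5) {
      lam <- random_lambda(fam)
      g <- num_grad(function(l) log_partition(fam, l), lam)
      expect_equal(g, unname(natural_to_mean(fam, lam)), tolerance = 1e-5,
                   label = paste("grad A for", fam$name))
    }
  }
})

test_that("natural/mean maps are mutually inverse on random points", {
  set.seed(12)
  for (fam in all_families(3)) {
    err <- replicate(100, {
      lam <- random_lambda(fam)
      max(abs(mean_to_natural(fam, natural_to_mean(fam, lam)) - lam))
    })
    expect_lt(max(err), 1e-6)
  }
})

test_that("textbook Gaussian correspondence and closed-form cases", {
  expect_equal(natural_to_mean(gaussian_family(1), c(0, -0.5)), c(0, 1))
  expect_equal(mean_to_natural(gaussian_family(1), c(0, 1)), c(0, -0.5))
  expect_equal(mean_to_natural(cb_family(1), 0.5), 0)
  # multivariate: natural (P^-1 m, -P^-1/2) <-> moments (m, P + m m')
  set.seed(13)
  m <- rnorm(3); P <- random_spd(3)
  lam <- gaussian_natural(m, P)
  fam <- gaussian_family(3)
  mo <- gaussian_moments(fam, lam)
  expect_equal(mo$m, m, tolerance = 1e-10)
  expect_equal(mo$P, P, tolerance = 1e-10)
  mu <- natural_to_mean(fam, lam)
  expect_equal(unvech(mu[4:9] / vech_weights(3), 3), P + tcrossprod(m),
               tolerance = 1e-9)
})

test_that("continuous Bernoulli limit at lambda -> 0 is the uniform mean", {
  expect_equal(natural_to_mean(cb_family(1), 1e-6), 0.5, tolerance = 1e-6)
  quad <- integrate(function(z) z * exp(1e-6 * z), 0, 1)$value /
    integrate(function(z) exp(1e-6 * z), 0, 1)$value
  expect_equal(natural_to_mean(cb_family(1), 1e-6), quad, tolerance = 1e-9)
})

test_that("samplers hit the right moments and support", {
  set.seed(14)
  n <- 1e5
  z <- ef_sample(gaussian_family(1), c(0, -0.5), n)
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  expect_lt(abs(mean(z^2) - 1), 3 * sqrt(2 / n))
  cb <- cb_family(1)
  zc <- ef_sample(cb, 4, n)
  expect_true(all(zc >= 0 & zc <= 1))
  mu4 <- integrate(function(z) z * exp(4 * z - log_partition(cb, 4)), 0, 1)$value
  se <- sd(zc) / sqrt(n)
  expect_lt(abs(mean(zc) - mu4), 3 * se)
  zg <- ef_sample(gamma_family(1), c(1, -1), n)
  expect_true(all(zg > 0))
  expect_lt(abs(mean(zg) - 2), 3 * sd(zg) / sqrt(n))
})

test_that("KL divergence: identity, closed form, Monte-Carlo agreement", {
  set.seed(15)
  fam1 <- gaussian_family(1)
  q <- gaussian_natural(0, matrix(1)); p <- gaussian_natural(1, matrix(1))
  expect_equal(kl_divergence(fam1, q, q), 0)
  expect_equal(kl_divergence(fam1, q, p), 0.5)
  for (fam in all_families(2)) {
    lq <- random_lambda(fam); lp <- random_lambda(fam)
    expect_gte(kl_divergence(fam, lq, lp), 0)
    n <- 1e5
    z <- ef_sample(fam, lq, n)
    diffs <- ef_log_density(fam, lq, z) - ef_log_density(fam, lp, z)
    se <- sd(diffs) / sqrt(n)
    expect_lt(abs(kl_divergence(fam, lq, lp) - mean(diffs)), 3 * se + 1e-10)
  }
})

test_that("entropy: closed forms and Monte-Carlo agreement", {
  expect_equal(ef_entropy(gaussian_family(1), c(0, -0.5)),
               0.5 * log(2 * pi * exp(1)), tolerance = 1e-10)
  expect_equal(ef_entropy(cb_family(1), 0), 0)
  set.seed(16)
  for (fam in all_families(2)[c("gaussian", "cb", "gamma")]) {
    lam <- random_lambda(fam)
    n <- 1e5
    z <- ef_sample(fam, lam, n)
    ld <- ef_log_density(fam, lam, z)
    se <- sd(ld) / sqrt(n)
    expect_lt(abs(ef_entropy(fam, lam) + mean(ld)), 3 * se + 1e-10)
  }
})

test_that("invalid natural parameters raise domain errors", {
  expect_error(log_partition(gaussian_family(1), c(0, 0.5)), "positive definite")
  expect_error(log_partition(gamma_family(1), c(-1.5, -1)), "Gamma naturals")
  expect_error(log_partition(gamma_family(1), c(1, 0.2)), "Gamma naturals")
  expect_error(mean_to_natural(cb_family(1), 1.2), "inside")
  expect_error(mean_to_natural(gamma_family(1), c(5, 1)), "Gamma")
})

test_that("densities integrate to one (1-d quadrature)", {
  for (case in list(list(fam = cb_family(1), lam = 3, lo = 0, hi = 1),
                    list(fam = gamma_family(1), lam = c(1.5, -2), lo = 0, hi = Inf),
                    list(fam = gaussian_family(1), lam = c(1, -1), lo = -Inf, hi = Inf))) {
    tot <- integrate(function(z) {
      exp(ef_log_density(case$fam, case$lam, matrix(z, ncol = 1)))
    }, case$lo, case$hi)$value
    expect_equal(tot, 1, tolerance = 1e-6)
  }
})
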