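# The variational predict / correct / update steps and the bound quantities,
# checked against closed forms, Monte-Carlo oracles and the exact Kalman filter.

test_that("variational prediction: closed form, constancy, and MC agreement", {
  fam <- gaussian_family(1)
  dyn <- linear_gaussian_dynamics(matrix(0.9), matrix(0.2))
  lamp <- gaussian_natural(1, matrix(0.5))
  # exact mode evaluates E[lambda_theta] in closed form: q_bar = N(0.9, 0.2)
  mo <- gaussian_moments(fam, variational_predict(fam, lamp, dyn))
  expect_equal(mo$m, 0.9, tolerance = 1e-12)
  expect_equal(mo$P[1, 1], 0.2, tolerance = 1e-12)
  # constant dynamics: lambda_bar = lambda0 regardless of q_prev and n_mc
  lam0 <- c(1.3, -0.7)
  cdyn <- constant_dynamics(cb_family(2), lam0)
  expect_equal(variational_predict(cb_family(2), c(0, 0), cdyn, n_mc = 3), lam0)
  expect_equal(variational_predict(cb_family(2), c(2, -2), cdyn, n_mc = 50), lam0)
  # MC mode converges to the exact mode
  set.seed(51)
  lam_mc <- variational_predict(fam, lamp, dyn, n_mc = 1e5, mode = "mc")
  lam_ex <- variational_predict(fam, lamp, dyn, mode = "exact")
  # SE of lambda_bar_1 = Qinv * A * sd(z)/sqrt(n)
  se1 <- (1 / 0.2) * 0.9 * sqrt(0.5) / sqrt(1e5)
  expect_lt(abs(lam_mc[1] - lam_ex[1]), 3 * se1)
  expect_equal(lam_mc[2], lam_ex[2], tolerance = 1e-12)
  expect_error(variational_predict(cb_family(1), 0, dyn), "family")
})

test_that("variance correction reproduces the Kalman prediction", {
  fam <- gaussian_family(1)
  dyn <- linear_gaussian_dynamics(matrix(0.9), matrix(0.2))
  lamp <- gaussian_natural(1, matrix(0.5))
  lb <- variational_predict(fam, lamp, dyn)
  lbc <- predict_correction(fam, lb, lamp, dyn)
  expect_equal(gaussian_moments(fam, lbc)$P[1, 1], 0.2 + 0.81 * 0.5,
               tolerance = 1e-12)
  # delta-like previous posterior: correction vanishes
  lamp0 <- gaussian_natural(1, matrix(1e-12))
  lb0 <- variational_predict(fam, lamp0, dyn)
  lbc0 <- predict_correction(fam, lb0, lamp0, dyn)
  expect_equal(gaussian_moments(fam, lbc0)$P[1, 1], 0.2, tolerance = 1e-10)
  # random 3-d system: corrected prediction equals the Kalman predict moments
  set.seed(52)
  mod <- random_lds(L = 3, N = 2)
  fam3 <- gaussian_family(3)
  dyn3 <- linear_gaussian_dynamics(mod$A, mod$Q)
  lamp3 <- gaussian_natural(rnorm(3), random_spd(3))
  prev <- gaussian_moments(fam3, lamp3)
  lbc3 <- predict_correction(fam3, variational_predict(fam3, lamp3, dyn3),
                             lamp3, dyn3)
  mo3 <- gaussian_moments(fam3, lbc3)
  expect_equal(mo3$m, drop(mod$A %*% prev$m), tolerance = 1e-10)
  expect_equal(mo3$P, mod$A %*% prev$P %*% t(mod$A) + mod$Q, tolerance = 1e-10)
})

test_that("conjugate update is exact Bayes", {
  fam <- gaussian_family(1)
  lik <- gaussian_likelihood(matrix(1), 0, matrix(1))
  post <- conjugate_update(fam, gaussian_natural(0, matrix(1)), 2, lik)
  mo <- gaussian_moments(fam, post)
  expect_equal(mo$m, 1, tolerance = 1e-12)
  expect_equal(mo$P[1, 1], 0.5, tolerance = 1e-12)
  # uninformative observation leaves the prior untouched
  likinf <- gaussian_likelihood(matrix(1), 0, matrix(1e12))
  post2 <- conjugate_update(fam, gaussian_natural(0.3, matrix(0.7)), 5, likinf)
  expect_equal(gaussian_moments(fam, post2)$m, 0.3, tolerance = 1e-6)
  expect_error(conjugate_update(cb_family(1), 0, 0.5,
                                gaussian_likelihood(matrix(1), 0, matrix(1))),
               "cvi_update")
})

test_that("full conjugate eVKF pass equals the Kalman filter", {
  set.seed(53)
  mod <- random_lds(L = 2, N = 2)
  sim <- simulate_lds(L = 2, N = 2, T = 100, A = mod$A, Q = mod$Q, C = mod$C,
                      b = mod$b, R = mod$R, m0 = mod$m0, P0 = mod$P0, seed = 54)
  kf <- kalman_filter(sim$ys, mod$A, mod$Q, mod$C, mod$b, mod$R, mod$m0, mod$P0)
  fit <- evkf_filter(sim$observations, linear_gaussian_dynamics(mod$A, mod$Q),
                     gaussian_likelihood(mod$C, mod$b, mod$R),
                     config = evkf_config(learn_steps_per_t = 0),
                     lambda0 = gaussian_natural(mod$m0, mod$P0))
  expect_equal(as.matrix(fit$records[c("m1", "m2", "v1", "v2")]),
               as.matrix(kf[c("m1", "m2", "v1", "v2")]), tolerance = 1e-8)
})

test_that("CVI with beta = 1 and one iteration reproduces the conjugate update", {
  set.seed(55)
  fam <- gaussian_family(2)
  lik <- gaussian_likelihood(matrix(rnorm(6), 3, 2), rnorm(3), random_spd(3))
  lam_bar <- gaussian_natural(rnorm(2), random_spd(2))
  y <- rnorm(3)
  conj <- conjugate_update(fam, lam_bar, y, lik)
  cvi <- cvi_update(fam, lam_bar, y, lik, iters = 1, beta = 1)
  expect_equal(as.numeric(cvi), conj, tolerance = 1e-10)
})

test_that("CVI handles the Poisson likelihood and its degenerate limits", {
  fam <- gaussian_family(1)
  # near-zero rate: observation carries no information
  lik0 <- poisson_likelihood(matrix(1), -20, dt = 1)
  lam_bar <- gaussian_natural(0.4, matrix(0.6))
  post <- cvi_update(fam, lam_bar, 0, lik0, iters = 20, beta = 0.8)
  expect_equal(as.numeric(post), lam_bar, tolerance = 1e-4)
  # ELBO is non-decreasing across CVI iterations (deterministic gradients)
  set.seed(56)
  lik <- poisson_likelihood(matrix(c(1.2, -0.8), 2, 1), c(0.1, 0.3), dt = 0.5)
  lam_bar2 <- gaussian_natural(0.2, matrix(0.8))
  y <- c(3, 0)
  elbos <- vapply(1:8, function(k) {
    attr(cvi_update(fam, lam_bar2, y, lik, iters = k, beta = 0.5), "elbo")
  }, numeric(1))
  expect_true(all(diff(elbos) > -1e-10))
})

test_that("CVI matches a dense grid search of the update ELBO", {
  set.seed(57)
  fam <- gaussian_family(1)
  for (rep in 1) {
    lam_bar <- gaussian_natural(rnorm(1), matrix(exp(rnorm(1, -0.5, 0.3))))
    lik <- poisson_likelihood(matrix(rnorm(3)), rnorm(3, 0.5), dt = 1)
    y <- rpois(3, 2)
    lam_star <- cvi_update(fam, lam_bar, y, lik, iters = 60, beta = 0.7)
    mo <- gaussian_moments(fam, as.numeric(lam_star))
    # grid over (mean, log variance) around the CVI solution
    ms <- seq(mo$m - 0.05, mo$m + 0.05, by = 1e-3)
    lvs <- seq(log(mo$P[1, 1]) - 0.05, log(mo$P[1, 1]) + 0.05, by = 1e-3)
    best <- c(NA, NA); bestv <- -Inf
    for (lv in lvs) {
      lams <- vapply(ms, function(m) {
        elbo_value(fam, gaussian_natural(m, matrix(exp(lv))), lam_bar, y, lik)
      }, numeric(1))
      if (max(lams) > bestv) {
        bestv <- max(lams); best <- c(ms[which.max(lams)], lv)
      }
    }
    expect_lt(abs(best[1] - mo$m), 2e-3)
    expect_lt(abs(best[2] - log(mo$P[1, 1])), 2e-3)
  }
})

test_that("free energy is minimized by the closed-form prediction", {
  set.seed(58)
  fam <- gaussian_family(1)
  dyn <- linear_gaussian_dynamics(matrix(0.8), matrix(0.3))
  lamp <- gaussian_natural(0.5, matrix(0.4))
  lam_bar <- variational_predict(fam, lamp, dyn)
  zs <- ef_sample(fam, lamp, 2000)
  # numerical minimization over (mean, log sd) with common random numbers
  obj <- function(par) {
    free_energy(fam, gaussian_natural(par[1], matrix(exp(2 * par[2]))),
                lamp, dyn, zs = zs)
  }
  opt <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  opt <- optim(opt$par, obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  lam_hat <- colMeans(eval_lambda(dyn, zs))   # MC minimizer given these samples
  mo_hat <- gaussian_moments(fam, lam_hat)
  expect_lt(abs(opt$par[1] - mo_hat$m), 1e-4)
  expect_lt(abs(exp(2 * opt$par[2]) - mo_hat$P[1, 1]), 1e-4)
  # and the closed form beats random perturbations
  f0 <- free_energy(fam, lam_hat, lamp, dyn, zs = zs)
  worse <- replicate(50, {
    free_energy(fam, lam_hat + rnorm(2, sd = 0.05) * c(1, -1) * runif(2),
                lamp, dyn, zs = zs)
  })
  expect_true(all(worse >= f0 - 1e-12))
})

test_that("free energy upper-bounds the KL to the marginalized transition", {
  set.seed(59)
  fam <- gaussian_family(1)
  dyn <- linear_gaussian_dynamics(matrix(0.8), matrix(0.3))
  lamp <- gaussian_natural(0.5, matrix(0.4))
  lam_bar <- variational_predict(fam, lamp, dyn)
  f <- free_energy(fam, lam_bar, lamp, dyn, n_mc = 2e4)
  # here E_qprev p_theta is Gaussian N(Am, Q + A P A') exactly
  lam_true <- gaussian_natural(0.8 * 0.5, matrix(0.3 + 0.64 * 0.4))
  expect_gte(f + 1e-10, kl_divergence(fam, lam_bar, lam_true))
})

test_that("bound gap: nonnegative, zero for constant/deterministic, closed form", {
  set.seed(60)
  fam <- gaussian_family(2)
  A <- matrix(c(0.7, 0.2, -0.3, 0.6), 2, 2)
  Q <- random_spd(2, 0.4)
  dyn <- linear_gaussian_dynamics(A, Q)
  m <- rnorm(2); P <- random_spd(2, 0.5)
  lamp <- gaussian_natural(m, P)
  # closed form: 1/2 tr(A' Q^-1 A P)
  gap_cf <- 0.5 * sum(diag(t(A) %*% solve(Q) %*% A %*% P))
  g <- bound_gap(fam, lamp, dyn, n_mc = 4e4)
  expect_lt(abs(as.numeric(g) - gap_cf), 3 * attr(g, "se"))
  # constant dynamics: exactly zero
  cdyn <- constant_dynamics(cb_family(1), 0.5)
  expect_equal(as.numeric(bound_gap(cb_family(1), 0.3, cdyn, n_mc = 100)), 0)
  # near-deterministic previous posterior: gap collapses
  lamp0 <- gaussian_natural(m, diag(2) * 1e-10)
  expect_lt(abs(as.numeric(bound_gap(fam, lamp0, dyn, n_mc = 1000))), 1e-8)
})

test_that("bound gap equals the two-step minus single-step bound difference", {
  set.seed(61)
  fam <- gaussian_family(1)
  dyn <- linear_gaussian_dynamics(matrix(0.8), matrix(0.3))
  lamp <- gaussian_natural(0.5, matrix(0.4))
  lik <- gaussian_likelihood(matrix(1), 0, matrix(0.5))
  y <- 1.2
  zs <- ef_sample(fam, lamp, 5e4)
  lam_bar <- colMeans(eval_lambda(dyn, zs))
  lam_q <- conjugate_update(fam, lam_bar, y, lik)   # any q works for Thm 2
  two_step <- elbo_value(fam, lam_q, lam_bar, y, lik)
  one_step <- single_step_bound(fam, lam_q, lamp, dyn, y, lik, zs = zs)
  gap <- bound_gap(fam, lamp, dyn, zs = zs)
  expect_equal(two_step - one_step, as.numeric(gap), tolerance = 1e-8)
  expect_gte(two_step - one_step, 0)
})

test_that("filter step contract: zero-information stream and determinism", {
  set.seed(62)
  dyn <- linear_gaussian_dynamics(matrix(0.9), matrix(0.1))
  lik_inf <- gaussian_likelihood(matrix(1), 0, matrix(1e12))
  st <- filter_init(dyn, lik_inf, evkf_config(learn_steps_per_t = 0))
  for (t in 1:5) {
    out <- filter_step(st, 0.3)
    st <- out$state
    expect_equal(st$lambda, out$lambda_bar, tolerance = 1e-6)
  }
  # identical seed + config => identical records
  sim <- simulate_vdp(T = 10, N = 8, seed = 63)
  run_once <- function() {
    set.seed(99)
    dynn <- nn_gaussian_dynamics(2, c(8, 8), Q = diag(2) * 0.0025, seed = 7)
    evkf_filter(sim$observations, dynn, sim$lik,
                config = evkf_config(n_mc_predict = 16, learn_n_mc = 16))
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1$records, r2$records)
  expect_identical(get_theta(r1$dyn), get_theta(r2$dyn))
})

test_that("Gamma-family prediction and correction widen the variance", {
  set.seed(64)
  fam <- gamma_family(1)
  dyn <- nn_gamma_dynamics(1, hidden = 8, seed = 12)
  lamp <- c(2, -1.5)   # Gamma(3, 1.5)
  lam_bar <- variational_predict(fam, lamp, dyn, n_mc = 2000)
  expect_true(lambda_ok <- !inherits(tryCatch(log_partition(fam, lam_bar),
                                              error = identity), "error"))
  lam_c <- predict_correction(fam, lam_bar, lamp, dyn, n_mc = 2000)
  mo_b <- natural_to_mean(fam, lam_bar)
  mo_c <- natural_to_mean(fam, lam_c)
  var_b <- (lam_bar[1] + 1) / lam_bar[2]^2
  var_c <- (lam_c[1] + 1) / lam_c[2]^2
  expect_equal(mo_c[2], mo_b[2], tolerance = 0.15)  # mean roughly preserved
  expect_gte(var_c, var_b * 0.99)                   # variance never shrinks
})
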