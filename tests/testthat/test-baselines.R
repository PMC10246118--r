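# Classical filters used as oracles: exact Kalman recursion, EKF, bootstrap
# particle filter, ensemble Kalman filter.

test_that("Kalman filter matches the brute-force joint-Gaussian conditional", {
  set.seed(31)
  mod <- random_lds(L = 2, N = 2)
  Tn <- 20
  sim <- simulate_lds(L = 2, N = 2, T = Tn, A = mod$A, Q = mod$Q, C = mod$C,
                      b = mod$b, R = mod$R, m0 = mod$m0, P0 = mod$P0, seed = 32)
  kf <- kalman_filter(sim$ys, mod$A, mod$Q, mod$C, mod$b, mod$R, mod$m0, mod$P0)
  # oracle: condition the (T*L + T*N)-dimensional joint Gaussian directly
  L <- 2; N <- 2
  Szz <- matrix(0, Tn * L, Tn * L)
  mz <- numeric(Tn * L)
  mprev <- mod$m0; Pprev <- mod$P0
  Apow <- diag(L)
  # joint latent covariance via the state recursion
  covs <- vector("list", Tn)
  means <- vector("list", Tn)
  P <- mod$P0
  m <- mod$m0
  for (t in 1:Tn) {
    m <- drop(mod$A %*% m)
    P <- mod$A %*% P %*% t(mod$A) + mod$Q
    means[[t]] <- m; covs[[t]] <- P
  }
  for (s in 1:Tn) {
    for (t in s:Tn) {
      blk <- covs[[s]]
      if (t > s) {
        Aprod <- diag(L)
        for (k in (s + 1):t) Aprod <- mod$A %*% Aprod
        blk <- Aprod %*% covs[[s]]
        Szz[((t - 1) * L + 1):(t * L), ((s - 1) * L + 1):(s * L)] <- blk
        Szz[((s - 1) * L + 1):(s * L), ((t - 1) * L + 1):(t * L)] <- t(blk)
      } else {
        Szz[((s - 1) * L + 1):(s * L), ((s - 1) * L + 1):(s * L)] <- blk
      }
    }
    mz[((s - 1) * L + 1):(s * L)] <- means[[s]]
  }
  Cbig <- kronecker(diag(Tn), mod$C)
  Syy <- Cbig %*% Szz %*% t(Cbig) + kronecker(diag(Tn), mod$R)
  Szy <- Szz %*% t(Cbig)
  yvec <- as.numeric(t(sim$ys)) - rep(mod$b, Tn)
  cond_mean <- mz + drop(Szy %*% solve(Syy, yvec - Cbig %*% mz))
  # final-step filtered mean equals the joint conditional at time T
  expect_equal(unlist(kf[Tn, c("m1", "m2")], use.names = FALSE),
               cond_mean[((Tn - 1) * L + 1):(Tn * L)], tolerance = 1e-8)
  cond_cov <- Szz - Szy %*% solve(Syy, t(Szy))
  expect_equal(attr(kf, "P")[, , Tn],
               cond_cov[((Tn - 1) * L + 1):(Tn * L), ((Tn - 1) * L + 1):(Tn * L)],
               tolerance = 1e-8)
})

test_that("pure prior recursion and Riccati fixed point", {
  # C = 0: beliefs follow m_t = A m_{t-1}, P_t = A P A' + Q
  A <- matrix(0.8); Q <- matrix(0.3)
  ys <- matrix(rnorm(10), 10, 1)
  kf <- kalman_filter(ys, A, Q, C = matrix(0), b = 0, R = matrix(1),
                      m0 = 1, P0 = matrix(0.5))
  m <- 1; P <- 0.5
  for (t in 1:10) {
    m <- 0.8 * m; P <- 0.64 * P + 0.3
    expect_equal(kf$m1[t], m, tolerance = 1e-12)
    expect_equal(kf$v1[t], P, tolerance = 1e-12)
  }
  # scalar stationary case converges to the Riccati fixed point
  set.seed(33)
  sim <- simulate_lds(T = 300, A = matrix(0.9), Q = matrix(0.1), C = matrix(1),
                      b = 0, R = matrix(0.5), seed = 34)
  kf2 <- kalman_filter(sim$ys, matrix(0.9), matrix(0.1), matrix(1), 0,
                       matrix(0.5), 0, matrix(1))
  Pfix <- 1
  for (i in 1:10000) {
    Pp <- 0.81 * Pfix + 0.1
    Pfix <- Pp - Pp^2 / (Pp + 0.5)
  }
  expect_equal(kf2$v1[300], Pfix, tolerance = 1e-10)
})

test_that("EKF equals Kalman exactly for linear-Gaussian models", {
  set.seed(35)
  mod <- random_lds(L = 2, N = 3)
  sim <- simulate_lds(L = 2, N = 3, T = 50, A = mod$A, Q = mod$Q, C = mod$C,
                      b = mod$b, R = mod$R, seed = 36)
  kf <- kalman_filter(sim$ys, mod$A, mod$Q, mod$C, mod$b, mod$R, mod$m0, mod$P0)
  ekf <- ekf_filter(sim$ys, linear_gaussian_dynamics(mod$A, mod$Q),
                    gaussian_likelihood(mod$C, mod$b, mod$R), mod$m0, mod$P0)
  expect_equal(as.matrix(ekf[-1]), as.matrix(kf[-1]), tolerance = 1e-10)
})

test_that("BPF posterior mean is within Monte-Carlo error of Kalman", {
  set.seed(37)
  sim <- simulate_lds(T = 40, A = matrix(0.9), Q = matrix(0.1), C = matrix(1),
                      b = 0, R = matrix(0.25), seed = 38)
  kf <- kalman_filter(sim$ys, matrix(0.9), matrix(0.1), matrix(1), 0,
                      matrix(0.25), 0, matrix(1))
  bpf <- bpf_filter(sim$ys, sim$dyn, sim$lik, 0, matrix(1), n_particles = 2e4)
  se <- sqrt(kf$v1 / 2e4) * 6   # conservative: resampling inflates variance
  expect_true(all(abs(bpf$m1 - kf$m1) < pmax(3 * se, 0.05)))
})

test_that("EnKF tracks the Kalman solution on a linear model", {
  set.seed(39)
  sim <- simulate_lds(T = 40, A = matrix(0.9), Q = matrix(0.1), C = matrix(1),
                      b = 0, R = matrix(0.25), seed = 40)
  kf <- kalman_filter(sim$ys, matrix(0.9), matrix(0.1), matrix(1), 0,
                      matrix(0.25), 0, matrix(1))
  enkf <- enkf_filter(sim$ys, sim$dyn, sim$lik, 0, matrix(1), n_ens = 5000)
  expect_lt(mean(abs(enkf$m1 - kf$m1)), 0.05)
})

test_that("near-perfect observation collapses all filters onto y", {
  set.seed(41)
  sim <- simulate_lds(T = 20, A = matrix(0.9), Q = matrix(0.1), C = matrix(1),
                      b = 0, R = matrix(1e-8), seed = 42)
  kf <- kalman_filter(sim$ys, matrix(0.9), matrix(0.1), matrix(1), 0,
                      matrix(1e-8), 0, matrix(1))
  expect_lt(max(abs(kf$m1 - sim$ys[, 1])), 1e-3)
  bpf <- bpf_filter(sim$ys, sim$dyn,
                    gaussian_likelihood(matrix(1), 0, matrix(1e-6)),
                    0, matrix(1), n_particles = 5000)
  expect_lt(max(abs(bpf$m1 - sim$ys[, 1])), 0.05)
})
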