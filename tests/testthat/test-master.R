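test_that("master-equation right-hand side reproduces hand-computed cases", {
  # all mass in monomers, no chipping: dc2/dt = c1^2, dc1/dt = -2 c1 N
  r <- master_rhs(cluster_distribution(10), 0)
  expect_equal(r$dcdt[1], -2)
  expect_equal(r$dcdt[2], 1)
  expect_equal(r$dcdt[3:10], rep(0, 8))
  # all mass in dimers, lambda = 1.5: chipping gives dc2 -= 2*lambda,
  # dc1 += 4*lambda (two monomers per dimer split); aggregation loss -2 c2 N
  c2 <- numeric(10); c2[2] <- 1
  r2 <- master_rhs(cluster_distribution(10, c = c2), 1.5)
  expect_equal(r2$dcdt[1], 4 * 1.5)
  expect_equal(r2$dcdt[2], -2 * 1.5 - 2)
  # negative input rejected
  bad <- cluster_distribution(10)
  bad$c[3] <- -0.1
  expect_error(master_rhs(bad, 1), "negative")
})

test_that("mass is conserved by the right-hand side for random states", {
  set.seed(11)
  for (rep in 1:20) {
    K <- 64
    cc <- rexp(K) * exp(-seq_len(K) / 8)
    d <- cluster_distribution(K, c = cc)
    lam <- runif(1, 0, 3)
    r <- master_rhs(d, lam)
    expect_equal(sum(seq_len(K) * r$dcdt) + r$dgel, 0, tolerance = 1e-10)
  }
})

test_that("generating-function transform of the RHS satisfies the Riccati form", {
  # pins the event-based chipping at per-cluster rate 2*lambda:
  # dC/dt = C^2 + 2 lambda (1-z)/z C + 2 lambda (1-z)^2/z N
  set.seed(7)
  K <- 64
  for (rep in 1:10) {
    cc <- numeric(K)
    cc[1:24] <- rexp(24) * exp(-(1:24) / 5)  # support << K: no truncation
    lam <- runif(1, 0.1, 2.5)
    r <- master_rhs(cluster_distribution(K, c = cc), lam)
    for (z in c(0.2, 0.5, 0.8, 0.95)) {
      zk <- z^seq_len(K)
      Cz <- sum((zk - 1) * cc)
      N <- sum(cc)
      dC_num <- sum((zk - 1) * r$dcdt)
      dC_ric <- Cz^2 + 2 * lam * (1 - z) / z * Cz +
        2 * lam * (1 - z)^2 / z * N
      expect_equal(dC_num, dC_ric, tolerance = 1e-8)
    }
  }
})

test_that("pure aggregation matches the constant-kernel closed form", {
  # K+ = 2, monomer start: c_k(t) = t^(k-1)/(1+t)^(k+1), N = 1/(1+t)
  d <- cluster_distribution(256)
  for (tt in c(0.5, 2, 5)) {
    d <- evolve_master(cluster_distribution(256), 0, t_end = tt,
                       rtol = 1e-10, atol = 1e-16)
    k <- 1:60
    exact <- tt^(k - 1) / (1 + tt)^(k + 1)
    expect_lt(max(abs(d$c[k] - exact)), 1e-6)
    expect_equal(sum(d$c), 1 / (1 + tt), tolerance = 1e-8)
  }
  # mass conservation through the integrator
  expect_equal(sum(seq_len(256) * d$c) + d$gel_mass, 1, tolerance = 1e-8)
  # t_end = 0 returns the input unchanged
  d0 <- cluster_distribution(64)
  expect_identical(evolve_master(d0, 1, t_end = 0), d0)
})

test_that("stationary N matches the analytic branches", {
  # sol side
  for (lam in c(1.2, 1.5, 2, 3)) {
    ss <- steady_state_master(lam, k_max = 2000)
    expect_equal(ss$N_inf, 1 - 1 / (2 * lam), tolerance = 1e-4)
    expect_identical(ss$phase, "sol")
  }
  # gel side: N = lambda/2, a finite mass fraction drains to the gel sink
  ss <- steady_state_master(0.5, k_max = 1e4)
  expect_equal(ss$N_inf, 0.25, tolerance = 4e-3)
  expect_identical(ss$phase, "gel")
  # branch continuity at the critical point
  expect_equal(steady_state_N(1), 0.5)
  expect_equal(1 - 1 / (2 * 1), 1 / 2)
})

test_that("series coefficients are the stationary state (two independent routes)", {
  lam <- 1.5
  sr <- series_coefficients(lam, k_max = 400)
  expect_true(all(sr >= 0))
  # hand-derived first coefficient: c1 = N - N^2/(2 lambda)
  N <- steady_state_N(lam)
  expect_equal(sr[1], N - N^2 / (2 * lam), tolerance = 1e-12)
  expect_equal(sum(sr), N, tolerance = 1e-8)
  # evolve to stationarity and compare where the ODE route is accurate
  ss <- steady_state_master(lam, k_max = 400, rtol = 1e-9, atol = 1e-18,
                            stat_tol = 1e-11)
  expect_true(ss$converged)
  kk <- 1:50
  expect_lt(max(abs(ss$dist$c[kk] - sr[kk]) / sr[kk]), 1e-4)
})

test_that("sol-phase cutoff size follows the closed form and diverges at the critical point", {
  expect_equal(cutoff_size(2), 1 / (2 * log(2) - log(3)), tolerance = 1e-12)
  expect_equal(cutoff_size(2), 3.476, tolerance = 1e-3)
  expect_error(cutoff_size(1), "sol side")
  expect_error(cutoff_size(0.7), "sol side")
  expect_gt(cutoff_size(1.0001), cutoff_size(1.001))
  # leading divergence exponent -2 from local log-log slopes
  delta <- c(1e-2, 1e-3, 1e-4)
  ls <- diff(log(cutoff_size(1 + delta))) / diff(log(delta))
  expect_equal(ls[2], -2, tolerance = 0.01)
})

test_that("tail exponents: -3/2 with cutoff (sol) and -5/2 (gel)", {
  # gel phase: pure power law, no exponential tail
  cg <- series_coefficients(0.5, k_max = 2000)
  fg <- tail_fit(seq_along(cg), cg, window = c(10, 1000), pin_kc = TRUE)
  expect_equal(fg$exponent, 2.5, tolerance = 0.1)
  # sol phase: power law with exponential cutoff; the leading -3/2 power is
  # resolved once the subleading (1 + B/k) correction is modelled
  lam <- 1.1
  kc <- cutoff_size(lam)
  cs <- series_coefficients(lam, k_max = 4000)
  fs <- tail_fit(seq_along(cs), cs, window = round(kc * c(2, 12)),
                 correction = TRUE)
  expect_equal(fs$exponent, 1.5, tolerance = 0.1)
  expect_equal(fs$k_c, kc, tolerance = 0.1 * kc)
})

test_that("tail_fit recovers known parameters", {
  k <- 1:500
  ck <- 2.7 * k^(-1.5) * exp(-k / 100)
  f <- tail_fit(k, ck)
  expect_equal(f$exponent, 1.5, tolerance = 1e-10)
  expect_equal(f$k_c, 100, tolerance = 1e-6)
  expect_equal(f$amplitude, 2.7, tolerance = 1e-8)
  # pure power law: cutoff reported unbounded
  f2 <- tail_fit(k, 5 * k^(-2.5))
  expect_identical(f2$k_c, Inf)
  expect_equal(f2$exponent, 2.5, tolerance = 1e-10)
  # multiplicative noise: tau recovered within 0.05 across replicates
  set.seed(21)
  taus <- replicate(100, {
    noisy <- ck * exp(rnorm(length(k), 0, 0.05))
    tail_fit(k, noisy, n_boot = 0)$exponent
  })
  expect_lt(abs(mean(taus) - 1.5), 0.05)
  expect_error(tail_fit(1:30, c(rep(1, 29), -1)), "non-positive")
})

test_that("phase label switches exactly once across the transition", {
  scan <- suppressWarnings(
    lambda_scan(seq(0.6, 1.6, by = 0.1), k_max = 2000))
  isgel <- scan$phase == "gel"
  expect_equal(sum(diff(isgel) != 0), 1)
  lc <- locate_transition(scan)
  expect_gt(lc, 0.8)
  expect_lt(lc, 1.2)
})
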