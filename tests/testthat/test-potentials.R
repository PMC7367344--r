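test_that("Mie potential has the standard normalisation and geometry", {
  pot <- mie_potential(n = 30, m = 20, epsilon = 2, sigma = 1.3)
  # zero crossing at sigma (up to the cutoff shift, which is tiny)
  expect_lt(abs(pair_energy(pot, 1.3) - (-pot$shift)), 1e-12)
  # minimum at (n/m)^(1/(n-m)) sigma with depth -epsilon: compare against a
  # numerical minimisation of the energy curve (independent route)
  opt <- optimize(function(r) pair_energy(pot, r), c(1.3, 1.6), tol = 1e-12)
  expect_equal(opt$minimum, 1.5^0.1 * 1.3, tolerance = 1e-6)
  expect_equal(opt$objective, -2 - pot$shift, tolerance = 1e-7)
  # unshifted well depth is exactly -epsilon to high accuracy
  expect_equal(gelkin:::.mie_raw(pot, minimum_radius(pot)), -2,
               tolerance = 1e-10)
})

test_that("Mie inflection radius matches the closed form for several exponent pairs", {
  # closed form r = (n(n+1)/(m(m+1)))^(1/(n-m)) sigma
  for (nm in list(c(30, 20), c(12, 6), c(50, 32))) {
    pot <- mie_potential(n = nm[1], m = nm[2])
    closed <- (nm[1] * (nm[1] + 1) / (nm[2] * (nm[2] + 1)))^(1 / (nm[1] - nm[2]))
    expect_equal(inflection_radius(pot), closed, tolerance = 1e-9)
  }
  # the (30, 20) pair reproduces the published bond criterion (31/14)^0.1 r_a
  expect_equal(inflection_radius(mie_potential()), (31 / 14)^0.1,
               tolerance = 1e-9)
})

test_that("forces are the negative analytic derivative of the energy", {
  h <- 1e-6
  for (pot in list(mie_potential(), mie_potential(n = 12, m = 6),
                   csw_potential(r_sw = 1.1, m = 500, n = 70))) {
    r <- seq(0.95, 1.3, by = 0.025)
    num <- -(pair_energy(pot, r + h) - pair_energy(pot, r - h)) / (2 * h)
    ana <- pair_force(pot, r)
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("continuous square well reproduces its defining form", {
  pot <- csw_potential(epsilon = 3, n = 700, m = 7000, r_sw = 1.1)
  # U(1) = 0: power term 1, sigmoid 0, minus 1
  expect_equal(pair_energy(pot, 1), 0 - pot$shift, tolerance = 1e-12)
  # mid-well: sigmoid saturated to -1, power term ~ 0 -> exactly -epsilon
  expect_equal(pair_energy(pot, (1 + 1.1) / 2), -3, tolerance = 3e-6)
  # far field -> 0
  expect_equal(pair_energy(pot, 1.45), 0, tolerance = 1e-10)
  expect_equal(pair_energy(pot, 10), 0)  # beyond cutoff
  # saturation handles huge exponents without overflow
  expect_true(is.finite(pair_energy(csw_potential(m = 1e6), 1.2)))
  # inflection sits just outside the outer wall
  infl <- inflection_radius(pot)
  expect_gt(infl, 1.1)
  expect_lt(infl, 1.15)
})

test_that("second virial quadrature matches the square-well closed form", {
  # ideal square well via a steep CSW: B2 -> (2pi/3) d^3 [1 - (lw^3-1)(e^(beta eps)-1)]
  eps <- 1.2; lw <- 1.15
  # the proxy square well has wall widths ~1/n and ~1/(m(lw-1)); the
  # residual of the closed form scales accordingly
  pot <- csw_potential(epsilon = eps, n = 1e6, m = 1e7, r_sw = lw,
                       cutoff = 1.6)
  for (kT in c(0.5, 1, 2)) {
    closed <- (2 * pi / 3) * (1 - (lw^3 - 1) * (exp(eps / kT) - 1))
    got <- second_virial(pot, kT, effective_diameter = "sigma")$B2
    expect_equal(got, closed, tolerance = 1e-4)
  }
  # pure repulsion limit: hard-sphere value (2pi/3) d^3, B2_reduced -> 1
  hs <- csw_potential(epsilon = 1e-12, n = 1e6, m = 1e7, r_sw = 1.01,
                      cutoff = 1.6)
  vr <- second_virial(hs, 1, effective_diameter = "sigma")
  expect_equal(vr$B2, 2 * pi / 3, tolerance = 1e-3)
  expect_equal(vr$B2_reduced, 1, tolerance = 1e-3)
})

test_that("Baxter mapping follows the adhesive-hard-sphere relation", {
  expect_equal(baxter_stickiness(-1.5), 0.1)
  expect_equal(baxter_stickiness(0.999), 1 / (4 * 0.001))
  expect_error(baxter_stickiness(1.2), "no net attraction")
  # monotone: stronger attraction (lower kT) -> smaller tau_B
  pot <- mie_potential()
  taus <- vapply(c(1, 1 / 1.5, 1 / 2, 1 / 2.5, 1 / 3),
                 function(kT) second_virial(pot, kT)$baxter_tau, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("Mie(30,20) at eps/kT = 2.5 maps onto stickiness near the gelation onset", {
  vir <- second_virial(mie_potential(), kT = 1 / 2.5)
  expect_lt(vir$B2_reduced, 1)
  expect_equal(vir$baxter_tau, 0.1, tolerance = 0.3)
})

test_that("CSW calibration matches the Mie second virial coefficient", {
  target <- mie_potential()
  kT <- 1 / 3
  csw <- calibrate_csw(target, kT)
  expect_equal(second_virial(csw, kT)$B2,
               second_virial(target, kT)$B2, tolerance = 1e-6)
  expect_equal(csw$n, 700)
  expect_equal(csw$m, 7000)
  # a weaker target calibrates to a much shallower well (the residual
  # depth compensates the softer Mie core at equal B2)
  weak <- mie_potential(epsilon = 1e-6)
  expect_lt(calibrate_csw(weak, kT)$epsilon, 0.5 * csw$epsilon)
  # width-matching route agrees on B2 too
  csw2 <- calibrate_csw(target, kT, match = "r_sw")
  expect_equal(second_virial(csw2, kT)$B2,
               second_virial(target, kT)$B2, tolerance = 1e-6)
})

test_that("potentials serialise to config lists and back", {
  for (pot in list(mie_potential(n = 24, m = 12, epsilon = 1.7),
                   csw_potential(epsilon = 0.8, r_sw = 1.09))) {
    back <- potential_from_config(potential_to_config(pot))
    expect_equal(pair_energy(back, c(1.02, 1.05, 1.2)),
                 pair_energy(pot, c(1.02, 1.05, 1.2)))
  }
})
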