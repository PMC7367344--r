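test_that("configuration validation and box geometry", {
  expect_error(sim_config(phi = 0.7), "phi")
  expect_error(sim_config(n_particles = 1), "n_particles")
  cfg <- sim_config(n_particles = 1000, phi = 0.12, seed = 1,
                    eq_duration = 0)
  L <- gelkin:::.box_edge(cfg)
  # phi = (pi/6)(n_a sigma_aa^3 + n_b sigma_bb^3)/L^3
  expect_equal(pi / 6 * (500 + 500 * 1.1^3) / L^3, 0.12, tolerance = 1e-12)
})

test_that("initial placement has no hard overlaps and Maxwellian speeds", {
  cfg <- sim_config(n_particles = 400, phi = 0.12, seed = 42,
                    eq_duration = 0)
  fr <- init_equilibrate(cfg)
  pr <- neighbor_pairs(fr, 0.97)
  expect_equal(nrow(pr), 0)  # no pair below 0.98 * sigma_aa
  # velocity components Gaussian at kT/m (a species has m = 1, kT = 1)
  va <- fr$velocities[fr$species == 0L, ]
  expect_equal(mean(va^2), 1, tolerance = 0.15)
  expect_lt(abs(mean(va)), 0.1)
  # equal species split with m_b = m_a (r_b/r_a)^3
  expect_equal(sum(fr$species == 0L), 200)
  expect_equal(unique(fr$mass[fr$species == 1L]), 1.1^3)
})

test_that("same seed gives identical trajectories, different seeds decorrelate", {
  cfg <- sim_config(n_particles = 150, phi = 0.12, eps_over_kT = 3,
                    seed = 9, eq_duration = 1, quench_duration = 2,
                    frame_interval = 1)
  f1 <- init_equilibrate(cfg)
  f2 <- init_equilibrate(cfg)
  expect_identical(f1$positions, f2$positions)
  t1 <- run_quench(f1, cfg)
  set.seed(cfg$seed)  # run_quench draws from the session RNG
  t1b <- run_quench(f1, cfg)
  set.seed(cfg$seed)
  t1c <- run_quench(f1, cfg)
  expect_identical(t1b$frames[[length(t1b$frames)]]$positions,
                   t1c$frames[[length(t1c$frames)]]$positions)
  cfg2 <- cfg; cfg2$seed <- 10
  f3 <- init_equilibrate(cfg2)
  expect_gt(max(abs(f1$positions - f3$positions)), 0.1)
})

test_that("damped free motion decays exponentially; thermostat equipartitions", {
  # free particles (dilute, no pairs in range): v(t) = v0 exp(-t/zeta)
  cfg <- sim_config(n_particles = 50, phi = 1e-6, seed = 3, dt = 0.005,
                    zeta = 1, eq_duration = 0)
  fr <- init_equilibrate(cfg)
  v0 <- fr$velocities
  nst <- 400L  # t = 2
  f2 <- langevin_step(fr, cfg, n_steps = nst, kT = 1, noise = FALSE,
                      friction = TRUE)
  expect_equal(f2$velocities, v0 * exp(-2), tolerance = 1e-6)
  # with noise: long-time <v^2> = 3 kT / m (exact for the OU update)
  f3 <- fr
  ke <- numeric(60)
  for (i in 1:60) {
    f3 <- langevin_step(f3, cfg, n_steps = 100, kT = 0.5)
    ke[i] <- mean(rowSums(f3$velocities^2) * f3$mass)
  }
  expect_equal(mean(ke[11:60]), 3 * 0.5, tolerance = 0.05)
})

test_that("free diffusion obeys the Einstein relation", {
  # D = kT zeta / m; MSD slope = 6 D for t >> zeta
  cfg <- sim_config(n_particles = 300, phi = 1e-7, seed = 6, dt = 0.01,
                    zeta = 0.5, eq_duration = 0)
  fr <- init_equilibrate(cfg)
  p0 <- fr$positions
  L <- fr$box
  f1 <- langevin_step(fr, cfg, n_steps = 1000, kT = 1)   # t = 10
  f2 <- langevin_step(f1, cfg, n_steps = 2000, kT = 1)   # t = 30
  msd_at <- function(f) {
    d <- f$positions - p0
    d <- d - L * round(d / L)
    mean(rowSums(d^2)[f$species == 0L])
  }
  D <- 1 * 0.5 / 1
  slope <- (msd_at(f2) - msd_at(f1)) / 20
  expect_equal(slope, 6 * D, tolerance = 0.15 * 6 * D)
})

test_that("velocity-Verlet limit conserves energy", {
  # steep (30, 20) cores need the finer step for strict NVE conservation;
  # production runs are thermostatted
  cfg <- sim_config(n_particles = 64, phi = 0.12, eps_over_kT = 1,
                    seed = 14, eq_duration = 2, dt = 0.00125)
  fr <- init_equilibrate(cfg)
  f0 <- langevin_step(fr, cfg, n_steps = 1, kT = 1)
  e0 <- attr(f0, "potential_energy") + attr(f0, "kinetic_energy")
  f1 <- langevin_step(f0, cfg, n_steps = 10000, kT = 1, noise = FALSE,
                      friction = FALSE)
  e1 <- attr(f1, "potential_energy") + attr(f1, "kinetic_energy")
  # drift per particle below 1e-4 epsilon over 1e4 steps
  expect_lt(abs(e1 - e0) / 64, 1e-4)
})

test_that("kinetic temperature tracks the target in the interacting liquid", {
  cfg <- sim_config(n_particles = 256, phi = 0.12, eps_over_kT = 1,
                    seed = 8, eq_duration = 5)
  fr <- init_equilibrate(cfg)
  temps <- numeric(60)
  for (i in seq_along(temps)) {
    fr <- langevin_step(fr, cfg, n_steps = 200, kT = 1)
    temps[i] <- 2 * attr(fr, "kinetic_energy") / (3 * 256)
  }
  expect_equal(mean(temps), 1, tolerance = 0.02)
})

test_that("neighbour search equals the all-pairs oracle and handles the boundary", {
  set.seed(2)
  n <- 180
  L <- 8
  pos <- matrix(runif(3 * n, 0, L), n, 3)
  pr <- neighbor_pairs(pos, 1.3, box = L)
  # brute-force oracle
  cnt <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - L * round(d / L)
    if (sqrt(sum(d^2)) < 1.3) cnt <- cnt + 1L
  }
  expect_equal(nrow(pr), cnt)
  expect_true(all(pr$dist < 1.3))
  # pair straddling the periodic boundary is found with image distance
  f <- particle_frame(rbind(c(0.2, 4, 4), c(7.9, 4, 4)), box = 8)
  pb <- neighbor_pairs(f, 1.0)
  expect_equal(nrow(pb), 1)
  expect_equal(pb$dist, 0.3, tolerance = 1e-12)
  expect_equal(abs(pb$off_x), 1)
  expect_error(neighbor_pairs(f, 4.1), "cutoff")
})

test_that("cell-list forces equal a direct R evaluation for a small system", {
  cfg <- sim_config(n_particles = 80, phi = 0.12, seed = 19,
                    eq_duration = 0.5)
  fr <- init_equilibrate(cfg)
  res <- gelkin:::pair_forces_cpp(fr$positions, fr$species, fr$box,
                                  gelkin:::.sim_pot(cfg))
  # R reference: loop over the pair list with the scalar force law
  pr <- neighbor_pairs(fr, 1.5)
  Fref <- matrix(0, 80, 3)
  peref <- 0
  sig <- c(1, 1.05, 1.1)
  for (e in seq_len(nrow(pr))) {
    i <- pr$i[e]; j <- pr$j[e]
    type <- fr$species[i] + fr$species[j] + 1L
    pot <- mie_potential(sigma = sig[type], cutoff = 1.5)
    fr_mag <- pair_force(pot, pr$dist[e])
    peref <- peref + pair_energy(pot, pr$dist[e])
    d <- fr$positions[i, ] - fr$positions[j, ]
    d <- d - fr$box * round(d / fr$box)
    Fref[i, ] <- Fref[i, ] + fr_mag * d / pr$dist[e]
    Fref[j, ] <- Fref[j, ] - fr_mag * d / pr$dist[e]
  }
  expect_equal(res$forces, Fref, tolerance = 1e-10)
  expect_equal(res$potential_energy, peref, tolerance = 1e-10)
})

test_that("quenches grow clusters at strong attraction and not at weak", {
  cfg <- sim_config(n_particles = 512, phi = 0.12, eps_over_kT = 4,
                    seed = 77, eq_duration = 5, quench_duration = 30,
                    frame_interval = 5)
  st <- init_equilibrate(cfg)
  # zero-duration quench returns the start frame only
  t0 <- run_quench(st, cfg, duration = 0)
  expect_length(t0$frames, 1)
  expect_identical(t0$frames[[1]], st)
  tr <- run_quench(st, cfg)
  m <- trajectory_metrics(tr, bond_criterion("simulation",
                                             potential = mie_potential()))
  # coordination number rises monotonically-ish and approaches saturation
  expect_gt(m$z[nrow(m)], 3)
  expect_gt(m$z[nrow(m)], m$z[1])
  late <- diff(m$z)[length(diff(m$z))] / diff(m$time)[1]
  early <- diff(m$z)[1] / diff(m$time)[1]
  expect_lt(late, early)  # growth slows as z saturates
})

test_that("extended-XYZ round trip is bit-exact", {
  cfg <- sim_config(n_particles = 60, phi = 0.12, eps_over_kT = 3,
                    seed = 4, eq_duration = 0.5, quench_duration = 1,
                    frame_interval = 0.5)
  st <- init_equilibrate(cfg)
  tr <- run_quench(st, cfg)
  path <- tempfile(fileext = ".extxyz")
  write_extxyz(tr, path)
  back <- read_extxyz(path)
  expect_equal(length(back$frames), length(tr$frames))
  last <- length(tr$frames)
  expect_identical(back$frames[[last]]$positions, tr$frames[[last]]$positions)
  expect_identical(back$frames[[last]]$velocities,
                   tr$frames[[last]]$velocities)
  expect_identical(back$frames[[1]]$species, tr$frames[[1]]$species)
  expect_identical(back$frames[[1]]$box, tr$frames[[1]]$box)
  unlink(path)
})

test_that("point-cloud CSV reader returns coordinates", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(x = runif(5), y = runif(5), z = runif(5), radius = 1)
  write.csv(df, path, row.names = FALSE)
  back <- read_point_cloud(path)
  expect_equal(back$x, df$x)
  expect_equal(back$radius, rep(1, 5))
  unlink(path)
})
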