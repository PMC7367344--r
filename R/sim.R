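#' Simulation configuration
#'
#' Parameters for Langevin-dynamics gelation runs of a binary mixture of
#' short-range attractive particles.  Units: lengths in \eqn{r_a}
#' (= contact distance of the small species), energies in the well depth
#' \eqn{\epsilon}, masses in \eqn{m_a}; the time unit is then
#' \eqn{t_s = \sqrt{m_a r_a^2/\epsilon} = 1}.  The attraction-to-thermal-energy
#' ratio \eqn{\epsilon/k_BT} is the control parameter; the simulator keeps
#' \eqn{\epsilon = 1} and sets \eqn{k_BT = (\epsilon/k_BT)^{-1}}, so a quench
#' deepens the effective attraction while time stays measured in \eqn{t_s}.
#'
#' @param n_particles total particle count (split equally between species).
#' @param phi volume fraction, computed from nominal radii
#'   \eqn{\sigma_{aa}/2} and \eqn{\sigma_{bb}/2}.
#' @param size_ratio contact-distance ratio \eqn{\sigma_{bb}/\sigma_{aa}}.
#' @param eps_over_kT attraction strength during the quench.
#' @param dt integration time step (units \eqn{t_s}).
#' @param zeta Langevin damping time (units \eqn{t_s}); the friction
#'   coefficient is \eqn{m/\zeta}.
#' @param eq_eps_over_kT attraction strength during equilibration (liquid
#'   state).
#' @param eq_duration equilibration time (units \eqn{t_s}).
#' @param quench_duration quench integration time (units \eqn{t_s}).
#' @param frame_interval trajectory sampling interval (units \eqn{t_s}).
#' @param fine_interval fine sampling interval for kinetics (units \eqn{t_s}).
#' @param potential `"mie"` or `"csw"`.
#' @param n,m Mie exponents (or CSW steepnesses via `csw_n`, `csw_m`).
#' @param cutoff pair-interaction cutoff (units \eqn{r_a}).
#' @param csw_n,csw_m,csw_r_sw continuous square-well parameters; `csw_r_sw`
#'   defaults to the Mie well geometry via [calibrate_csw()] conventions.
#' @param seed integer RNG seed recorded with the trajectory.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_particles = 32768, phi = 0.12, size_ratio = 1.1,
                       eps_over_kT = 4, dt = 0.0025, zeta = 1,
                       eq_eps_over_kT = 1, eq_duration = 100,
                       quench_duration = 500, frame_interval = 1,
                       fine_interval = 0.05, potential = c("mie", "csw"),
                       n = 30, m = 20, cutoff = 1.5, csw_n = 700,
                       csw_m = 7000, csw_r_sw = NULL, seed = NULL) {
  potential <- match.arg(potential)
  stopifnot(n_particles >= 2, phi > 0, phi < 0.64, size_ratio >= 1,
            dt > 0, zeta > 0, eps_over_kT > 0, cutoff > 1)
  structure(list(
    n_particles = as.integer(n_particles), phi = phi,
    size_ratio = size_ratio, eps_over_kT = eps_over_kT, dt = dt, zeta = zeta,
    eq_eps_over_kT = eq_eps_over_kT, eq_duration = eq_duration,
    quench_duration = quench_duration, frame_interval = frame_interval,
    fine_interval = fine_interval, potential = potential, n = n, m = m,
    cutoff = cutoff, csw_n = csw_n, csw_m = csw_m, csw_r_sw = csw_r_sw,
    seed = seed), class = "sim_config")
}

# pair-potential parameter list handed to the C++ kernel
.sim_pot <- function(config) {
  s_aa <- 1
  s_bb <- config$size_ratio
  s_ab <- 0.5 * (s_aa + s_bb)  # additive mixing
  if (config$potential == "mie") {
    list(family = "mie", epsilon = 1, n = config$n, m = config$m,
         sigma_pair = c(s_aa, s_ab, s_bb), cutoff = config$cutoff)
  } else {
    r_sw <- config$csw_r_sw
    if (is.null(r_sw))
      r_sw <- inflection_radius(mie_potential(n = config$n, m = config$m))
    list(family = "csw", epsilon = 1, n = config$csw_n, m = config$csw_m,
         sigma_pair = c(s_aa, s_ab, s_bb), r_sw = r_sw,
         cutoff = config$cutoff)
  }
}

# reference R-level pair potential for species pair type (1 = aa, 2 = ab, 3 = bb)
.pair_potential_for <- function(config, type = 1) {
  sp <- .sim_pot(config)
  s <- sp$sigma_pair[type]
  if (config$potential == "mie")
    mie_potential(n = config$n, m = config$m, epsilon = 1, sigma = s,
                  cutoff = config$cutoff)
  else
    csw_potential(epsilon = 1, n = config$csw_n, m = config$csw_m,
                  r_sw = sp$r_sw, cutoff = config$cutoff / s)
}

#' Particle frame
#'
#' A snapshot of all particles: wrapped positions, velocities, species,
#' radii and masses, plus the periodic box edge and the time stamp.
#'
#' @param positions N x 3 matrix, wrapped into `[0, L)`.
#' @param velocities N x 3 matrix.
#' @param species integer vector (0 = small species a, 1 = large species b).
#' @param box box edge length L.
#' @param time time stamp (units \eqn{t_s}).
#' @param radii per-particle nominal radii; default from species.
#' @param mass per-particle masses; default equal material density
#'   (\eqn{m \propto r^3}).
#' @param size_ratio contact-distance ratio used for the defaults.
#' @return An object of class `"particle_frame"`.
#' @export
particle_frame <- function(positions, velocities = NULL, species = NULL,
                           box, time = 0, radii = NULL, mass = NULL,
                           size_ratio = 1.1) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, box > 0)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(species)) species <- integer(n)
  if (is.null(radii)) radii <- ifelse(species == 0L, 0.5, 0.5 * size_ratio)
  if (is.null(mass)) mass <- ifelse(species == 0L, 1, size_ratio^3)
  if (any(positions < 0 | positions >= box))
    positions <- positions - box * floor(positions / box)
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 species = as.integer(species), radii = radii, mass = mass,
                 box = box, time = time),
            class = "particle_frame")
}

#' @export
print.particle_frame <- function(x, ...) {
  cat(sprintf("particle_frame: %d particles, box %.4g, t = %.4g t_s\n",
              nrow(x$positions), x$box, x$time))
  invisible(x)
}

.box_edge <- function(config) {
  n_b <- config$n_particles %/% 2L
  n_a <- config$n_particles - n_b
  # phi = (pi/6) (n_a sigma_aa^3 + n_b sigma_bb^3) / L^3
  (pi / 6 * (n_a + n_b * config$size_ratio^3) / config$phi)^(1 / 3)
}

#' Initialise and equilibrate a liquid configuration
#'
#' Places the binary mixture by random sequential insertion with overlap
#' rejection, draws Maxwell-Boltzmann velocities, and evolves the system in
#' the liquid state (default \eqn{\epsilon/k_BT = 1}) for `eq_duration` so
#' that the returned frame is a structureless liquid from which a quench can
#' be started.
#'
#' @param config a [sim_config()].
#' @param max_attempts insertion attempts per particle before giving up.
#' @return A `"particle_frame"` at the end of equilibration.
#' @export
init_equilibrate <- function(config, max_attempts = 5000) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_particles
  L <- .box_edge(config)
  n_b <- n %/% 2L
  species <- c(rep(0L, n - n_b), rep(1L, n_b))
  sig <- c(1, 0.5 * (1 + config$size_ratio), config$size_ratio)

  pos <- matrix(0, n, 3)
  min_gap <- 0.98
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- stats::runif(3, 0, L)
      ok <- TRUE
      if (i > 1) {
        d <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, cand)
        d <- d - L * round(d / L)
        r2 <- rowSums(d * d)
        need <- (min_gap * sig[species[seq_len(i - 1)] + species[i] + 1])^2
        ok <- all(r2 >= need)
      }
      if (ok) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("random insertion failed for particle ", i,
           "; volume fraction too high for rejection placement")
  }

  mass <- ifelse(species == 0L, 1, config$size_ratio^3)
  kT_eq <- 1 / config$eq_eps_over_kT
  vel <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(kT_eq / mass)

  frame <- particle_frame(pos, vel, species, box = L, time = 0,
                          size_ratio = config$size_ratio)
  if (config$eq_duration > 0) {
    steps <- max(1L, round(config$eq_duration / config$dt))
    res <- langevin_run_cpp(frame$positions, frame$velocities, frame$species,
                            frame$mass, L, .sim_pot(config), config$dt,
                            steps, config$zeta, kT_eq, save_every = 0L)
    frame$positions <- res$positions
    frame$velocities <- res$velocities
  }
  frame
}

#' Advance a frame by Langevin dynamics
#'
#' Integrates the inertial Langevin equation
#' \deqn{m\,\dot v = F_{pair} - (m/\zeta)\,v + f_B(t),\qquad
#'       \langle f_B(t) f_B(t')\rangle = 2 m k_B T\,\delta(t-t')/\zeta,}
#' using the BAOAB splitting (velocity-Verlet drift/kick with an exact
#' Ornstein-Uhlenbeck update of the velocities).  With `friction = FALSE`
#' and `noise = FALSE` the scheme reduces to plain velocity Verlet.
#'
#' @param frame a `"particle_frame"`.
#' @param config a [sim_config()].
#' @param n_steps number of time steps.
#' @param kT thermal energy; default from `config$eps_over_kT`.
#' @param noise,friction logical switches for the stochastic and damping
#'   parts (used by integrator checks).
#' @return The advanced `"particle_frame"`.
#' @export
langevin_step <- function(frame, config, n_steps = 1, kT = NULL,
                          noise = TRUE, friction = TRUE) {
  stopifnot(inherits(frame, "particle_frame"), inherits(config, "sim_config"))
  if (is.null(kT)) kT <- 1 / config$eps_over_kT
  res <- langevin_run_cpp(frame$positions, frame$velocities, frame$species,
                          frame$mass, frame$box, .sim_pot(config), config$dt,
                          as.integer(n_steps), config$zeta, kT,
                          save_every = 0L, noise = noise, friction = friction)
  frame$positions <- res$positions
  frame$velocities <- res$velocities
  frame$time <- frame$time + n_steps * config$dt
  attr(frame, "potential_energy") <- res$potential_energy
  attr(frame, "kinetic_energy") <- res$kinetic_energy
  frame
}

#' All particle pairs within a cutoff
#'
#' Exact set of unordered pairs with minimum-image distance below `cutoff`,
#' found with cell lists (with an all-pairs fallback for small boxes).
#' `off_*` are the periodic image offsets of particle `i` relative to `j`,
#' needed to unwrap clusters across the boundary.
#'
#' @param frame a `"particle_frame"` (or an N x 3 matrix together with `box`).
#' @param cutoff pair distance threshold; must be `< box/2`.
#' @param box box edge (only when `frame` is a bare matrix).
#' @return A data.frame with columns `i`, `j`, `dist`, `off_x`, `off_y`,
#'   `off_z`.
#' @export
neighbor_pairs <- function(frame, cutoff, box = NULL) {
  if (inherits(frame, "particle_frame")) {
    pos <- frame$positions
    box <- frame$box
  } else {
    pos <- as.matrix(frame)
    stopifnot(!is.null(box))
  }
  as.data.frame(neighbor_pairs_cpp(pos, box, cutoff))
}

#' Quench a liquid into the gel regime
#'
#' Switches the attraction to `config$eps_over_kT` and integrates for
#' `duration`, storing a frame every `frame_interval` together with a log of
#' potential energy, kinetic temperature and time.
#'
#' @param start equilibrated `"particle_frame"` (see [init_equilibrate()]).
#' @param config a [sim_config()].
#' @param duration,frame_interval override the config values.
#' @return A `"gel_trajectory"`: list with `frames` (list of
#'   `"particle_frame"`), `log` (data.frame) and `config`.
#' @export
run_quench <- function(start, config, duration = config$quench_duration,
                       frame_interval = config$frame_interval) {
  stopifnot(inherits(start, "particle_frame"), inherits(config, "sim_config"))
  if (duration <= 0) {
    return(structure(list(frames = list(start), config = config,
                          log = data.frame(time = start$time, pe = NA_real_,
                                           temperature = NA_real_)),
                     class = "gel_trajectory"))
  }
  kT <- 1 / config$eps_over_kT
  save_every <- max(1L, round(frame_interval / config$dt))
  n_steps <- max(save_every, round(duration / config$dt))
  res <- langevin_run_cpp(start$positions, start$velocities, start$species,
                          start$mass, start$box, .sim_pot(config), config$dt,
                          as.integer(n_steps), config$zeta, kT,
                          save_every = save_every)
  n_dof <- 3 * nrow(start$positions)
  frames <- vector("list", length(res$frames) + 1)
  frames[[1]] <- start
  for (k in seq_along(res$frames)) {
    f <- start
    f$positions <- res$frames[[k]]
    f$velocities <- if (k == length(res$frames)) res$velocities else
      matrix(NA_real_, nrow(start$positions), 3)
    f$time <- start$time + res$log_time[k]
    frames[[k + 1]] <- f
  }
  structure(list(
    frames = frames, config = config,
    log = data.frame(time = start$time + res$log_time, pe = res$log_pe,
                     temperature = 2 * res$log_ke / n_dof)),
    class = "gel_trajectory")
}

#' @export
print.gel_trajectory <- function(x, ...) {
  cat(sprintf("gel_trajectory: %d frames, N = %d, box %.4g\n",
              length(x$frames), nrow(x$frames[[1]]$positions),
              x$frames[[1]]$box))
  invisible(x)
}
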