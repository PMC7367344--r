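#' Mie pair potential
#'
#' Generalised Lennard-Jones potential
#' \deqn{U(r) = C\,\epsilon\left[(\sigma/r)^n - (\sigma/r)^m\right],\qquad
#'       C = \frac{n}{n-m}\left(\frac{n}{m}\right)^{m/(n-m)},}
#' normalised so that \eqn{U(\sigma) = 0} and the minimum depth is exactly
#' \eqn{-\epsilon}.  The potential is truncated at `cutoff` and shifted in
#' energy so that \eqn{U(r_c) = 0} (no force shift).  The default exponents
#' \eqn{(n, m) = (30, 20)} give a narrow attractive well of width
#' \eqn{\approx 0.08\,\sigma}, the short-range regime typical of critical
#' Casimir or depletion-driven colloidal attraction.
#'
#' @param n repulsive exponent (dimensionless), `n > m`.
#' @param m attractive exponent (dimensionless), `m > 0`.
#' @param epsilon well depth (energy units).
#' @param sigma zero-crossing distance (length units, `r_a`).
#' @param cutoff truncation radius (length units, `r_a`).
#' @return An object of class `c("mie_potential", "pair_potential")`.
#' @examples
#' pot <- mie_potential()
#' pair_energy(pot, minimum_radius(pot))  # -epsilon (up to the cutoff shift)
#' @export
mie_potential <- function(n = 30, m = 20, epsilon = 1, sigma = 1,
                          cutoff = 1.5 * sigma) {
  stopifnot(n > m, m > 0, epsilon > 0, sigma > 0, cutoff > sigma)
  prefac <- (n / (n - m)) * (n / m)^(m / (n - m))
  pot <- structure(
    list(n = n, m = m, epsilon = epsilon, sigma = sigma, cutoff = cutoff,
         prefac = prefac, shift = 0),
    class = c("mie_potential", "pair_potential"))
  pot$shift <- .mie_raw(pot, cutoff)
  pot
}

.mie_raw <- function(pot, r) {
  x <- pot$sigma / r
  # factored form avoids Inf - Inf for deeply overlapping cores
  pot$prefac * pot$epsilon * x^pot$m * (x^(pot$n - pot$m) - 1)
}

#' Continuous square-well pair potential
#'
#' Smooth sigmoid approximation of a square well,
#' \deqn{U(r) = \frac{\epsilon}{2}\left[\left(\frac{1}{r}\right)^{n} +
#'   \frac{1 - e^{-m(r-1)(r-r_{sw})}}{1 + e^{-m(r-1)(r-r_{sw})}} - 1\right],}
#' with `r` in units of the contact distance.  The sigmoid term equals
#' \eqn{\tanh[m(r-1)(r-r_{sw})/2]} and is evaluated in that form so that it
#' saturates to \eqn{\pm 1} without overflow.  The well floor is \eqn{-\epsilon}
#' for \eqn{1 < r < r_{sw}}, the wall steepnesses are set by `m` (outer wall)
#' and `n` (repulsive core).
#'
#' @param epsilon well depth (energy units).
#' @param n repulsive-core steepness (dimensionless).
#' @param m outer-wall steepness (dimensionless).
#' @param r_sw well width, i.e. the outer edge of the well in units of the
#'   contact distance.
#' @param cutoff truncation radius (units of the contact distance).
#' @return An object of class `c("csw_potential", "pair_potential")`.
#' @export
csw_potential <- function(epsilon = 1, n = 700, m = 7000, r_sw = 1.083,
                          cutoff = 1.5) {
  stopifnot(epsilon >= 0, n > 0, m > 0, r_sw > 1, cutoff > r_sw)
  pot <- structure(
    list(epsilon = epsilon, n = n, m = m, r_sw = r_sw, cutoff = cutoff,
         sigma = 1, shift = 0),
    class = c("csw_potential", "pair_potential"))
  pot$shift <- .csw_raw(pot, cutoff)
  pot
}

.csw_raw <- function(pot, r) {
  x <- pot$m * (r - 1) * (r - pot$r_sw)
  0.5 * pot$epsilon * ((1 / r)^pot$n + tanh(0.5 * x) - 1)
}

#' Pair energy and radial force
#'
#' `pair_energy()` returns the truncated-and-shifted pair energy;
#' `pair_force()` returns the radial force \eqn{f = -dU/dr} (positive =
#' repulsive), computed analytically.  Both are vectorised over `r` and
#' return 0 beyond the cutoff.
#'
#' @param pot a `pair_potential` object.
#' @param r separation(s), must be positive.
#' @return Numeric vector of energies or forces.
#' @export
pair_energy <- function(pot, r) UseMethod("pair_energy")

#' @rdname pair_energy
#' @export
pair_force <- function(pot, r) UseMethod("pair_force")

#' @export
pair_energy.mie_potential <- function(pot, r) {
  if (any(r <= 0)) stop("separation must be positive")
  ifelse(r < pot$cutoff, .mie_raw(pot, r) - pot$shift, 0)
}

#' @export
pair_force.mie_potential <- function(pot, r) {
  if (any(r <= 0)) stop("separation must be positive")
  x <- pot$sigma / r
  ifelse(r < pot$cutoff,
         pot$prefac * pot$epsilon * x^pot$m *
           (pot$n * x^(pot$n - pot$m) - pot$m) / r,
         0)
}

#' @export
pair_energy.csw_potential <- function(pot, r) {
  if (any(r <= 0)) stop("separation must be positive")
  ifelse(r < pot$cutoff, .csw_raw(pot, r) - pot$shift, 0)
}

#' @export
pair_force.csw_potential <- function(pot, r) {
  if (any(r <= 0)) stop("separation must be positive")
  x <- pot$m * (r - 1) * (r - pot$r_sw)
  sech2 <- ifelse(abs(0.5 * x) > 350, 0, 1 / cosh(0.5 * x)^2)
  dx <- pot$m * (2 * r - 1 - pot$r_sw)
  dU <- 0.5 * pot$epsilon * (-pot$n * (1 / r)^pot$n / r + 0.5 * sech2 * dx)
  ifelse(r < pot$cutoff, -dU, 0)
}

#' Mie energy and force at a separation
#'
#' Convenience wrapper returning both the energy and the radial force of a
#' Mie potential at separation `r`.
#'
#' @param r separation (length units), positive.
#' @param pot a [mie_potential()].
#' @return List with elements `energy` and `force`.
#' @export
mie_energy_force <- function(r, pot) {
  list(energy = pair_energy(pot, r), force = pair_force(pot, r))
}

#' Location of the potential minimum
#' @param pot a `pair_potential` object.
#' @return Separation at which the energy is minimal.
#' @export
minimum_radius <- function(pot) UseMethod("minimum_radius")

#' @export
minimum_radius.mie_potential <- function(pot) {
  (pot$n / pot$m)^(1 / (pot$n - pot$m)) * pot$sigma
}

#' @export
minimum_radius.csw_potential <- function(pot) {
  # well floor is flat; use the centre of the well
  0.5 * (1 + pot$r_sw)
}

#' Inflection point of the pair potential
#'
#' Smallest separation beyond the well minimum at which \eqn{U''(r) = 0},
#' found by bracketed root search on the analytic second derivative.  This
#' radius is the bond criterion used to define directly contacting particles
#' in simulations.
#'
#' @param pot a `pair_potential` object.
#' @return Separation of the inflection point.
#' @export
inflection_radius <- function(pot) UseMethod("inflection_radius")

#' @export
inflection_radius.mie_potential <- function(pot) {
  d2 <- function(r) {
    x <- pot$sigma / r
    pot$prefac * pot$epsilon *
      (pot$n * (pot$n + 1) * x^pot$n - pot$m * (pot$m + 1) * x^pot$m) / r^2
  }
  lo <- minimum_radius(pot)
  hi <- pot$cutoff
  if (d2(lo) <= 0 || d2(hi * (1 - 1e-9)) >= 0) {
    # expand cautiously; for standard exponent pairs the bracket always holds
    if (sign(d2(lo)) == sign(d2(hi * (1 - 1e-9))))
      stop("no sign change of U'' between the minimum and the cutoff")
  }
  stats::uniroot(d2, c(lo, hi * (1 - 1e-9)), tol = 1e-14)$root
}

#' @export
inflection_radius.csw_potential <- function(pot) {
  d2 <- function(r) {
    x <- pot$m * (r - 1) * (r - pot$r_sw)
    sech2 <- ifelse(abs(0.5 * x) > 350, 0, 1 / cosh(0.5 * x)^2)
    th <- tanh(0.5 * x)
    dx <- pot$m * (2 * r - 1 - pot$r_sw)
    0.5 * pot$epsilon * (pot$n * (pot$n + 1) * (1 / r)^pot$n / r^2 +
                           pot$m * sech2 - 0.5 * dx^2 * sech2 * th)
  }
  # U'' > 0 at the well centre/outer wall, turns negative just outside it
  lo <- pot$r_sw
  w <- (pot$r_sw - 1) / 10
  hi <- lo + w
  while (d2(hi) > 0 && hi < pot$cutoff) hi <- hi + w
  if (d2(hi) > 0) stop("no sign change of U'' between the well and the cutoff")
  stats::uniroot(d2, c(lo, hi), tol = 1e-14)$root
}

#' Characteristic radii of a potential (integration split points)
#' @param pot a `pair_potential` object.
#' @return Increasing numeric vector of radii in (0, cutoff).
#' @keywords internal
characteristic_radii <- function(pot) UseMethod("characteristic_radii")

#' @export
characteristic_radii.mie_potential <- function(pot)
  c(0.5 * pot$sigma, pot$sigma, minimum_radius(pot))

#' @export
characteristic_radii.csw_potential <- function(pot)
  c(0.5, 1, 0.5 * (1 + pot$r_sw), pot$r_sw)

#' Second virial coefficient and Baxter stickiness
#'
#' Computes \deqn{B_2 = 2\pi \int_0^\infty \left(1 - e^{-U(r)/k_BT}\right)
#' r^2\,dr} for a truncated pair potential by adaptive quadrature split at the
#' potential's characteristic radii, together with the reduced virial
#' coefficient \eqn{B_2^* = B_2 / B_2^{HS}(d)} and the Baxter adhesive-hard-
#' sphere stickiness implied by \eqn{B_2^* = 1 - 1/(4\tau_B)}.
#'
#' The effective hard-sphere diameter `d` is by default the Barker-Henderson
#' diameter \eqn{d = \int_0^{\sigma_0}(1 - e^{-U(r)/k_BT})\,dr} computed over
#' the repulsive branch (up to the zero crossing \eqn{\sigma_0}); setting
#' `effective_diameter = "sigma"` uses the nominal contact distance instead.
#'
#' @param pot a `pair_potential` object (truncated and shifted at its cutoff).
#' @param kT thermal energy (same units as the well depth).
#' @param effective_diameter `"barker-henderson"` (default) or `"sigma"`.
#' @return An object of class `"virial_result"`: list with `B2`,
#'   `B2_reduced`, `effective_diameter`, `baxter_tau` (NA when there is no net
#'   attraction) and `kT`.
#' @export
second_virial <- function(pot, kT,
                          effective_diameter = c("barker-henderson", "sigma")) {
  stopifnot(kT > 0)
  effective_diameter <- match.arg(effective_diameter)
  beta <- 1 / kT
  f <- function(r) (1 - exp(-beta * pair_energy(pot, r))) * r^2
  brk <- sort(unique(c(0, characteristic_radii(pot), pot$cutoff)))
  B2 <- 0
  for (i in seq_len(length(brk) - 1)) {
    quad <- tryCatch(
      stats::integrate(f, brk[i], brk[i + 1], rel.tol = 1e-10,
                       abs.tol = 1e-12, subdivisions = 400L),
      error = function(e) stop("second-virial quadrature failed on [",
                               signif(brk[i], 6), ", ", signif(brk[i + 1], 6),
                               "]: ", conditionMessage(e)))
    B2 <- B2 + quad$value
  }
  B2 <- 2 * pi * B2

  if (effective_diameter == "barker-henderson") {
    # zero crossing of the shifted potential
    sigma0 <- stats::uniroot(function(r) pair_energy(pot, r),
                             c(0.5 * pot$sigma, minimum_radius(pot)),
                             tol = 1e-14)$root
    g <- function(r) 1 - exp(-beta * pair_energy(pot, r))
    d_eff <- stats::integrate(g, 0, sigma0, rel.tol = 1e-10,
                              subdivisions = 400L)$value
  } else {
    d_eff <- pot$sigma
  }
  b2hs <- 2 * pi / 3 * d_eff^3
  b2r <- B2 / b2hs
  structure(list(B2 = B2, B2_reduced = b2r, effective_diameter = d_eff,
                 baxter_tau = if (b2r < 1) 1 / (4 * (1 - b2r)) else NA_real_,
                 kT = kT),
            class = "virial_result")
}

#' Baxter stickiness from a reduced second virial coefficient
#'
#' Maps a net-attractive potential onto the adhesive-hard-sphere model of
#' matched second virial coefficient: \eqn{\tau_B = 1 / [4(1 - B_2^*)]}.
#' Small \eqn{\tau_B} means strong adhesion; colloidal gelation sets in
#' around \eqn{\tau_B \approx 0.1}.
#'
#' @param x a `"virial_result"` or a numeric reduced virial coefficient.
#' @return The stickiness parameter \eqn{\tau_B}.
#' @export
baxter_stickiness <- function(x) {
  b2r <- if (inherits(x, "virial_result")) x$B2_reduced else as.numeric(x)
  if (b2r >= 1)
    stop("reduced B2 >= 1: no net attraction to map onto stickiness")
  1 / (4 * (1 - b2r))
}

#' Calibrate a continuous square well against a Mie potential
#'
#' Constructs a continuous square-well potential whose second virial
#' coefficient at temperature `kT` equals that of a target Mie potential,
#' by root-finding on either the well depth (`match = "epsilon"`, default)
#' or the well width (`match = "r_sw"`).  The default well width is taken
#' from the target's well geometry (distance from the zero crossing to the
#' inflection point), expressed in units of the contact distance so that
#' per-species-pair widths scale with the pair contact distance.
#'
#' @param target a [mie_potential()].
#' @param kT thermal energy at which the virial coefficients are matched.
#' @param match parameter to solve for: `"epsilon"` or `"r_sw"`.
#' @param r_sw well width; default derived from the target geometry.
#' @param n,m steepness parameters of the continuous square well.
#' @return A [csw_potential()] (distances in units of the contact distance).
#' @export
calibrate_csw <- function(target, kT, match = c("epsilon", "r_sw"),
                          r_sw = NULL, n = 700, m = 7000) {
  stopifnot(inherits(target, "mie_potential"), kT > 0)
  match <- match.arg(match)
  b2_target <- second_virial(target, kT)$B2 / target$sigma^3
  cutoff <- target$cutoff / target$sigma
  if (is.null(r_sw))
    r_sw <- inflection_radius(target) / target$sigma
  if (match == "epsilon") {
    obj <- function(eps)
      second_virial(csw_potential(epsilon = eps, n = n, m = m, r_sw = r_sw,
                                  cutoff = cutoff), kT)$B2 - b2_target
    if (obj(1e-12) < 0)
      return(csw_potential(epsilon = 0, n = n, m = m, r_sw = r_sw,
                           cutoff = cutoff))
    hi <- max(2 * target$epsilon, 4 * kT)
    while (obj(hi) > 0 && hi < 1e3 * kT) hi <- 2 * hi
    if (obj(hi) > 0) stop("no well depth in bracket matches the target B2")
    eps <- stats::uniroot(obj, c(1e-12, hi), tol = 1e-10)$root
    csw_potential(epsilon = eps, n = n, m = m, r_sw = r_sw, cutoff = cutoff)
  } else {
    obj <- function(w)
      second_virial(csw_potential(epsilon = target$epsilon, n = n, m = m,
                                  r_sw = w, cutoff = cutoff), kT)$B2 -
        b2_target
    lo <- 1 + 2e-3
    hi <- cutoff - 1e-3
    if (sign(obj(lo)) == sign(obj(hi)))
      stop("no well width in bracket matches the target B2")
    w <- stats::uniroot(obj, c(lo, hi), tol = 1e-10)$root
    csw_potential(epsilon = target$epsilon, n = n, m = m, r_sw = w,
                  cutoff = cutoff)
  }
}

#' @export
print.virial_result <- function(x, ...) {
  cat("Second virial coefficient\n")
  cat(sprintf("  B2            = %.6g (volume units)\n", x$B2))
  cat(sprintf("  d_eff         = %.6g\n", x$effective_diameter))
  cat(sprintf("  B2 / B2_HS    = %.6g\n", x$B2_reduced))
  cat(sprintf("  Baxter tau_B  = %.6g\n", x$baxter_tau))
  invisible(x)
}

#' Serialise / restore a pair potential to plain-list (YAML-ready) form
#' @param pot a `pair_potential` object.
#' @return A named list of scalar fields.
#' @export
potential_to_config <- function(pot) {
  if (inherits(pot, "mie_potential"))
    list(family = "mie", n = pot$n, m = pot$m, epsilon = pot$epsilon,
         sigma = pot$sigma, cutoff = pot$cutoff)
  else
    list(family = "csw", n = pot$n, m = pot$m, epsilon = pot$epsilon,
         r_sw = pot$r_sw, cutoff = pot$cutoff)
}

#' @rdname potential_to_config
#' @param config a named list as produced by [potential_to_config()].
#' @export
potential_from_config <- function(config) {
  if (identical(config$family, "mie"))
    mie_potential(n = config$n, m = config$m, epsilon = config$epsilon,
                  sigma = config$sigma, cutoff = config$cutoff)
  else if (identical(config$family, "csw"))
    csw_potential(epsilon = config$epsilon, n = config$n, m = config$m,
                  r_sw = config$r_sw, cutoff = config$cutoff)
  else stop("unknown potential family: ", config$family)
}
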