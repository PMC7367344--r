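#' Cluster-size distribution state
#'
#' State of the coagulation-fragmentation master equation: concentrations
#' `c[k]` of clusters of `k` particles per unit volume for `k = 1..k_max`,
#' normalised so the initial first moment is 1, plus a gel-mass accumulator
#' that absorbs mass aggregating past `k_max` (a non-interacting sink
#' standing in for the giant cluster).
#'
#' @param k_max truncation size.
#' @param c initial concentrations; default all mass in monomers.
#' @param gel_mass initial gel mass.
#' @param time initial time.
#' @return An object of class `"cluster_distribution"`.
#' @export
cluster_distribution <- function(k_max = 1e4, c = NULL, gel_mass = 0,
                                 time = 0) {
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 1)
  if (is.null(c)) {
    c <- numeric(k_max)
    c[1] <- 1
  }
  stopifnot(length(c) == k_max, all(c >= 0), gel_mass >= 0)
  structure(list(c = c, gel_mass = gel_mass, time = time, k_max = k_max),
            class = "cluster_distribution")
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat(sprintf(
    "cluster_distribution: k_max = %d, t = %.4g, N = %.6g, M1 = %.6g, gel = %.6g\n",
    x$k_max, x$time, sum(x$c), sum(seq_along(x$c) * x$c), x$gel_mass))
  invisible(x)
}

#' Time derivative of the master equation
#'
#' Right-hand side of the cluster-population master equation with constant
#' aggregation kernel \eqn{K^+_{ij} = 2}: gain
#' \eqn{\tfrac{1}{2}\sum_{i+j=k} 2 c_i c_j}, loss \eqn{2 c_k N}, plus
#' event-based single-particle chipping: every cluster of size \eqn{k \ge 2}
#' emits one monomer at rate \eqn{2\lambda} (a dimer split yields two
#' monomers).  Merges past `k_max` deposit their mass in the gel
#' accumulator.
#'
#' @param dist a [cluster_distribution()].
#' @param lambda chipping parameter \eqn{\lambda \ge 0}.
#' @return List with `dcdt` (vector) and `dgel` (gel mass flux).
#' @export
master_rhs <- function(dist, lambda) {
  stopifnot(inherits(dist, "cluster_distribution"), lambda >= 0)
  if (any(dist$c < 0)) stop("negative concentrations in the input state")
  me_rhs_cpp(dist$c, lambda)
}

#' Integrate the master equation
#'
#' Adaptive Runge-Kutta (Cash-Karp 4/5) integration of [master_rhs()];
#' aggregation terms are evaluated by fast convolution so one evaluation
#' costs \eqn{O(k_{max}\log k_{max})}.
#'
#' @param dist initial state, or NULL for a monomer start at `k_max`.
#' @param lambda chipping parameter.
#' @param t_end integration time (0 returns the input unchanged).
#' @param k_max truncation used when `dist` is NULL.
#' @param rtol,atol local error tolerances.
#' @return The evolved `"cluster_distribution"`.
#' @export
evolve_master <- function(dist = NULL, lambda = 0, t_end, k_max = 1e4,
                          rtol = 1e-8, atol = 1e-14) {
  if (is.null(dist)) dist <- cluster_distribution(k_max)
  stopifnot(inherits(dist, "cluster_distribution"), t_end >= 0, lambda >= 0)
  if (any(dist$c < 0)) stop("negative concentrations in the input state")
  if (t_end == 0) return(dist)
  res <- me_evolve_cpp(dist$c, dist$gel_mass, lambda, t_end, rtol, atol)
  cluster_distribution(dist$k_max, c = pmax(res$c, 0),
                       gel_mass = res$gel_mass,
                       time = dist$time + res$time)
}

#' Closed-form stationary total cluster concentration
#'
#' \eqn{N_\infty = 1 - (2\lambda)^{-1}} on the sol side (\eqn{\lambda > 1})
#' and \eqn{N_\infty = \lambda/2} on the gel side (\eqn{\lambda < 1}); the
#' two branches meet at the critical point \eqn{\lambda_c = 1} where both
#' give 1/2.
#'
#' @param lambda chipping parameter (> 0).
#' @return Stationary \eqn{N_\infty}.
#' @export
steady_state_N <- function(lambda) {
  stopifnot(all(lambda > 0))
  ifelse(lambda >= 1, 1 - 1 / (2 * lambda), lambda / 2)
}

#' Sol-side cutoff scale extended through the critical region
#'
#' The sol-phase cutoff expression evaluated with \eqn{|2\lambda - 1|};
#' on the gel side it plays the role of the crossover size beyond which the
#' population can only be a draining (coarsening) front, never a stationary
#' tail.  Returns `Inf` at the critical point and 0 deep in the gel phase
#' where the expression loses meaning.
#'
#' @param lambda chipping parameter (> 0).
#' @return The crossover size scale.
#' @keywords internal
.cutoff_scale <- function(lambda) {
  if (lambda == 1) return(Inf)
  x <- 2 * log(lambda) - log(abs(2 * lambda - 1))
  if (!is.finite(x) || x <= 0) 0 else 1 / x
}

#' Stationary state of the master equation
#'
#' Integrates from a monomer start and determines the stationary total
#' cluster concentration \eqn{N_\infty} and the phase.  A state that
#' becomes stationary within the budget (all \eqn{|dc_k/dt|} below
#' `stat_tol`) is classified directly: sol when the finite-cluster
#' population retains the full mass, gel when a finite fraction has
#' drained into the giant-cluster sink.  Near the critical point the
#' approach to stationarity is critically slowed, so \eqn{N(t)} is sampled
#' at three geometrically spaced checkpoints and accelerated by Aitken's
#' \eqn{\Delta^2} extrapolation; the phase is then whichever analytic
#' stationary branch (\eqn{1 - (2\lambda)^{-1}} sol, \eqn{\lambda/2} gel)
#' the extrapolated \eqn{N_\infty} matches, ties (the critical point
#' itself, where the branches meet) going to sol.
#'
#' @param lambda chipping parameter (> 0).
#' @param k_max truncation size (should satisfy \eqn{k_{max} \gg k_c}).
#' @param t_max integration budget; default scales with the crossover size
#'   so near-critical points get longer runs.
#' @param stat_tol stationarity threshold on \eqn{\max_k |dc_k/dt|}.
#' @param gel_threshold gel mass fraction that forces the gel label.
#' @param rtol,atol integrator tolerances.
#' @return List with `dist`, `N_inf` (extrapolated when not stationary),
#'   `gel_mass`, `phase`, `converged` (TRUE when stationarity was reached)
#'   and `exit` (`"stationary"` or `"extrapolated"`).
#' @export
steady_state_master <- function(lambda, k_max = 1e4, t_max = NULL,
                                stat_tol = 1e-9, gel_threshold = 0.05,
                                rtol = 1e-7, atol = 1e-14) {
  stopifnot(lambda > 0)
  k_max <- as.integer(k_max)
  if (lambda > 1) {
    kc <- cutoff_size(lambda)
    if (k_max < 10 * kc)
      warning(sprintf(
        "k_max = %d is not large against the cutoff size k_c = %.3g; %s",
        k_max, kc, "the stationary state will be truncated"))
  }
  if (is.null(t_max))
    t_max <- min(4000, max(if (lambda < 1) 1800 else 600,
                           40 * .cutoff_scale(lambda)))

  checkpoints <- t_max * c(1 / 9, 1 / 3, 1)
  Ns <- rep(NA_real_, 3)
  c_cur <- cluster_distribution(k_max)$c
  gel <- 0
  t_cur <- 0
  stationary <- FALSE
  for (s in 1:3) {
    res <- me_evolve_cpp(c_cur, gel, lambda, checkpoints[s] - t_cur,
                         rtol, atol, stat_tol = stat_tol)
    c_cur <- res$c
    gel <- max(res$gel_mass, 0)  # clip integrator round-off
    t_cur <- t_cur + res$time
    Ns[s] <- sum(c_cur)
    if (isTRUE(res$stationary)) {
      stationary <- TRUE
      break
    }
  }
  N_inf <- Ns[if (stationary) s else 3]
  exit <- "stationary"
  if (!stationary) {
    # Aitken delta^2 acceleration of the log-spaced N(t) checkpoints: the
    # approach to stationarity is a power law in t, which is geometric
    # across 3x-spaced checkpoints
    d1 <- Ns[2] - Ns[1]
    d2 <- Ns[3] - Ns[2]
    if (is.finite(d1) && is.finite(d2) && abs(d2) < abs(d1) && d2 != 0)
      N_inf <- Ns[3] - d2^2 / (d2 - d1)
    exit <- "extrapolated"
  }

  N_sol <- 1 - 1 / (2 * lambda)
  N_gel <- lambda / 2
  phase <- if (gel > gel_threshold) "gel"
    else if (abs(N_inf - N_gel) < abs(N_inf - N_sol)) "gel" else "sol"

  list(dist = cluster_distribution(k_max, c = pmax(c_cur, 0),
                                   gel_mass = gel, time = t_cur),
       N_inf = N_inf, gel_mass = gel, phase = phase,
       converged = stationary, exit = exit)
}

#' Steady-state cluster-mass distribution from the generating function
#'
#' At stationarity the generating function \eqn{C(z) = \sum_j (z^j - 1) c_j}
#' satisfies a quadratic (Riccati fixed point); the branch analytic at
#' \eqn{z = 0} is expanded in powers of \eqn{z} by an explicit recursion on
#' the quadratic relation, with no numerical differentiation.  In the sol
#' phase the coefficients decay as \eqn{k^{-3/2} e^{-k/k_c}}; in the gel
#' phase as \eqn{k^{-5/2}} with no exponential cutoff.
#'
#' @param lambda chipping parameter (> 0).
#' @param k_max number of coefficients to extract.
#' @param N stationary total concentration; defaults to the closed-form
#'   branch value [steady_state_N()].
#' @return Numeric vector `c[1..k_max]` of stationary concentrations.
#' @export
series_coefficients <- function(lambda, k_max = 1e4, N = NULL) {
  stopifnot(lambda > 0, k_max >= 1)
  if (is.null(N)) N <- steady_state_N(lambda)
  ck <- me_series_cpp(lambda, N, as.integer(k_max))
  bad <- ck < -1e-8 * max(abs(ck))
  if (any(bad))
    stop("negative series coefficients: no physical branch at lambda = ",
         lambda)
  pmax(ck, 0)
}

#' Sol-phase exponential cutoff size
#'
#' \deqn{k_c = \left\{2\log(\lambda/\lambda_c) -
#'   \log\left[2(\lambda/\lambda_c) - 1\right]\right\}^{-1},\qquad
#'   \lambda_c = 1,} the cluster size beyond which the stationary sol-phase
#' distribution is exponentially suppressed.  Diverges as
#' \eqn{(\lambda - 1)^{-2}} at the critical point.
#'
#' @param lambda chipping parameter, `> 1` (sol side).
#' @return The cutoff size \eqn{k_c}.
#' @export
cutoff_size <- function(lambda) {
  if (any(lambda <= 1))
    stop("the exponential cutoff is defined on the sol side (lambda > 1)")
  1 / (2 * log(lambda) - log(2 * lambda - 1))
}

#' Fit a power law with exponential cutoff
#'
#' Least-squares fit of \eqn{c_k = A\,k^{-\tau} e^{-k/k_c}} in log space.
#' The model is linear in \eqn{(\log A, \tau, 1/k_c)}, so the fit is exact
#' for noiseless data; `pin_kc = TRUE` fixes \eqn{k_c = \infty} (pure power
#' law).  A fitted non-positive \eqn{1/k_c} is reported as `k_c = Inf`
#' (unbounded within the window).
#'
#' @param k cluster sizes (support points).
#' @param ck concentrations or counts at `k` (must be positive within the
#'   window).
#' @param window inclusive `c(kmin, kmax)` fit range; default all of `k`.
#' @param pin_kc fix the cutoff at infinity.
#' @param correction include a first-order corrections-to-scaling factor
#'   \eqn{(1 + B/k)} (fitted by nonlinear least squares, seeded from the
#'   linear fit).  Near the critical point the subleading power carries a
#'   large amplitude, and the leading exponent is only recovered once this
#'   correction is modelled.
#' @param counts treat `ck` as sampled event counts per size (zeros
#'   allowed) and fit by Poisson regression, the unbiased estimator for
#'   histogram data — least squares on log counts censors the empty sizes
#'   in the far tail and inflates the fitted cutoff.
#' @param n_boot bootstrap replicates for standard errors.
#' @return A `"scaling_fit"` with `exponent` (\eqn{\tau}), `k_c`,
#'   `amplitude`, `se` (on \eqn{\tau}), `window`, `n`.
#' @export
tail_fit <- function(k, ck, window = NULL, pin_kc = FALSE,
                     correction = FALSE, counts = FALSE, n_boot = 200) {
  stopifnot(length(k) == length(ck))
  if (is.null(window)) window <- range(k)
  sel <- k >= window[1] & k <= window[2]
  if (sum(sel) < 20) stop("need at least 20 support points in the window")
  if (counts) {
    kk <- k[sel]; nn <- ck[sel]
    fit <- if (pin_kc) stats::glm(nn ~ log(kk), family = stats::poisson())
           else stats::glm(nn ~ log(kk) + kk, family = stats::poisson())
    cf <- stats::coef(fit)
    sef <- sqrt(diag(stats::vcov(fit)))
    return(structure(list(
      exponent = -unname(cf[2]),
      k_c = if (pin_kc || cf[3] >= 0) Inf else -1 / unname(cf[3]),
      amplitude = exp(unname(cf[1])), se = unname(sef[2]),
      window = window, n = sum(sel), counts = TRUE),
      class = "scaling_fit"))
  }
  if (any(ck[sel] <= 0))
    stop("non-positive concentrations inside the fit window")
  x <- log(k[sel]); y <- log(ck[sel]); kk <- k[sel]
  fit <- if (pin_kc) stats::lm(y ~ x) else stats::lm(y ~ x + kk)
  cf <- stats::coef(fit)
  tau <- -unname(cf["x"])
  kc <- if (pin_kc) Inf else {
    slope <- unname(cf["kk"])
    # a cutoff far beyond the data window is indistinguishable from none
    if (slope >= 0 || -1 / slope > 1e3 * max(kk)) Inf else -1 / slope
  }
  if (correction) {
    df <- data.frame(x = x, kk = kk, y = y)
    start <- list(A = unname(cf[1]), tau = tau, B = mean(kk) / 10)
    nfit <- if (pin_kc)
      stats::nls(y ~ A - tau * x + log(1 + B / kk), data = df,
                 start = start)
    else
      stats::nls(y ~ A - tau * x - kk / kcf + log(1 + B / kk), data = df,
                 start = c(start, list(kcf = if (is.finite(kc)) kc else
                                               max(kk))))
    ncf <- stats::coef(nfit)
    tau <- unname(ncf["tau"])
    if (!pin_kc) kc <- unname(ncf["kcf"])
    cf[1] <- ncf["A"]
  }
  boots <- if (n_boot <= 0) NA_real_ else replicate(n_boot, {
    idx <- sample.int(length(x), replace = TRUE)
    f <- if (pin_kc) stats::lm(y[idx] ~ x[idx]) else
      stats::lm(y[idx] ~ x[idx] + kk[idx])
    -unname(stats::coef(f)[2])
  })
  structure(list(exponent = tau, k_c = kc, amplitude = exp(unname(cf[1])),
                 se = stats::sd(boots), window = window, n = sum(sel),
                 correction = correction),
            class = "scaling_fit")
}

#' Scan the chipping parameter across the sol-gel transition
#'
#' Evolves the master equation to stationarity on a grid of \eqn{\lambda},
#' classifies each point (sol versus gel), and records the stationary
#' \eqn{N_\infty} and gel mass.  [locate_transition()] returns the midpoint
#' of the single phase switch.
#'
#' @param lambdas grid of chipping parameters.
#' @param k_max truncation size.
#' @param ... further arguments to [steady_state_master()].
#' @return A data.frame with one row per lambda: `lambda`, `N_inf`,
#'   `gel_mass`, `phase`, `converged`, `N_sol`, `N_gel` (branch formulas).
#' @export
lambda_scan <- function(lambdas = seq(0.2, 3, by = 0.02), k_max = 1e4, ...) {
  rows <- lapply(lambdas, function(l) {
    ss <- steady_state_master(l, k_max = k_max, ...)
    data.frame(lambda = l, N_inf = ss$N_inf, gel_mass = ss$gel_mass,
               phase = ss$phase, converged = ss$converged)
  })
  out <- do.call(rbind, rows)
  out$N_sol <- 1 - 1 / (2 * out$lambda)
  out$N_gel <- out$lambda / 2
  out
}

#' @rdname lambda_scan
#' @param scan a data.frame from [lambda_scan()].
#' @return `locate_transition()`: the estimated critical \eqn{\lambda_c}
#'   (midpoint between the last gel and first sol grid point).
#' @export
locate_transition <- function(scan) {
  stopifnot(all(c("lambda", "phase") %in% names(scan)))
  scan <- scan[order(scan$lambda), ]
  isgel <- scan$phase == "gel"
  flips <- which(diff(isgel) != 0)
  if (length(flips) == 0) stop("no phase change within the scanned range")
  if (length(flips) > 1)
    warning("phase label switches more than once; using the first switch")
  0.5 * (scan$lambda[flips[1]] + scan$lambda[flips[1] + 1])
}
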