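#' Fit a power-law divergence with unknown critical point
#'
#' Fits \eqn{y = A\,(x_c - x)^{-s}} to data approaching a critical value
#' \eqn{x_c} from below, by grid search over candidate critical values: for
#' each candidate, a linear regression of \eqn{\log y} on
#' \eqn{\log(x_c - x)} is performed and the candidate maximising the
#' log-log linearity (\eqn{R^2}) is kept.  Standard errors come from a
#' block bootstrap over observations, respecting the temporal correlation
#' of frames taken from a single growth run.
#'
#' This is the estimator behind the percolation evidence: the fraction of
#' particles in the largest cluster diverges as
#' \eqn{f_z \sim (z_c - z)^{-\sigma}} and the correlation length as
#' \eqn{\xi \sim (z_c - z)^{-\nu}} on approach to the critical coordination
#' number \eqn{z_c}.
#'
#' @param x control variable (e.g. mean coordination number per frame).
#' @param y diverging observable (positive).
#' @param candidates candidate critical values; default a grid just above
#'   `max(x)`.
#' @param window optional inclusive range of `y` used in the fit (the
#'   divergence form only holds on the rising branch; for a bounded
#'   fraction like `f_z` use e.g. `c(0.02, 0.5)`).
#' @param n_boot bootstrap replicates.
#' @param block bootstrap block length (consecutive observations).
#' @return A `"scaling_fit"` with `critical`, `exponent` (positive
#'   divergence exponent \eqn{s}), `amplitude`, `se` (on the exponent),
#'   `se_critical`, `r_squared`, `window`, `n`.
#' @export
fit_divergence <- function(x, y, candidates = NULL, window = NULL,
                           n_boot = 200, block = 10) {
  keep <- is.finite(x) & is.finite(y) & y > 0
  if (!is.null(window)) keep <- keep & y >= window[1] & y <= window[2]
  x <- x[keep]; y <- y[keep]
  if (length(x) < 6) stop("fewer than 6 usable points for a divergence fit")
  if (is.null(candidates)) {
    span <- max(diff(range(x)), 1e-6)
    candidates <- max(x) + span * seq(0.005, 1, length.out = 120)
  }
  candidates <- candidates[candidates > max(x)]
  if (length(candidates) == 0) stop("no candidate critical value above the data")

  fit_at <- function(xc, xx, yy) {
    lx <- log(xc - xx)
    f <- stats::lm(log(yy) ~ lx)
    res <- stats::residuals(f)
    tss <- sum((log(yy) - mean(log(yy)))^2)
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         r2 = if (tss > 0) 1 - sum(res^2) / tss else 1)
  }
  pick <- function(xx, yy) {
    r2 <- vapply(candidates, function(xc) fit_at(xc, xx, yy)$r2, numeric(1))
    best <- which.max(r2)
    c(xc = candidates[best], r2 = r2[best])
  }

  best <- pick(x, y)
  f <- fit_at(best["xc"], x, y)

  nb <- length(x)
  boots <- if (n_boot <= 0) NA_real_ else replicate(n_boot, {
    starts <- sample.int(max(1, nb - block + 1),
                         ceiling(nb / block), replace = TRUE)
    idx <- unlist(lapply(starts, function(s) s:min(nb, s + block - 1)))
    idx <- idx[seq_len(min(length(idx), nb))]
    b <- tryCatch(pick(x[idx], y[idx]), error = function(e) c(NA, NA))
    if (anyNA(b)) c(NA, NA) else
      c(fit_at(b[1], x[idx], y[idx])$slope, b[1])
  })
  structure(list(critical = unname(best["xc"]),
                 exponent = -f$slope,
                 amplitude = exp(f$intercept),
                 se = if (is.matrix(boots))
                   stats::sd(-boots[1, ], na.rm = TRUE) else NA_real_,
                 se_critical = if (is.matrix(boots))
                   stats::sd(boots[2, ], na.rm = TRUE) else NA_real_,
                 r_squared = unname(best["r2"]),
                 window = if (is.null(window)) range(y) else window,
                 n = length(x)),
            class = "scaling_fit")
}

#' Critical attraction from the saturation coordination number
#'
#' Below the critical attraction \eqn{\epsilon_c} the coordination number
#' saturates at \eqn{z_{max}(\epsilon) < z_c}; on approach to
#' \eqn{\epsilon_c} from below the deficit closes as a power law,
#' \eqn{z_c - z_{max} \propto (\epsilon_c - \epsilon)^{\theta}}.  The fit
#' searches a grid over \eqn{(\epsilon_c, z_c)} and regresses the deficit
#' in log-log space for each candidate pair, keeping the most linear one.
#'
#' @param eps attraction strengths (sub-critical branch).
#' @param z_max saturation coordination numbers at each attraction.
#' @param eps_c_grid,z_c_grid candidate grids; defaults bracket the data.
#' @param n_boot bootstrap replicates over the points.
#' @return A `"scaling_fit"` with `critical` (\eqn{\epsilon_c}),
#'   `exponent` (\eqn{\theta}), `z_c`, `amplitude`, `se`, `r_squared`, `n`.
#' @export
fit_zmax_vs_attraction <- function(eps, z_max, eps_c_grid = NULL,
                                   z_c_grid = NULL, n_boot = 200) {
  keep <- is.finite(eps) & is.finite(z_max)
  eps <- eps[keep]; z_max <- z_max[keep]
  if (length(eps) < 4) stop("need at least 4 sub-critical attraction points")
  o <- order(eps)
  if (any(diff(z_max[o]) < -0.25))
    warning("z_max is not monotone in the attraction strength beyond noise")
  if (is.null(eps_c_grid)) {
    span <- diff(range(eps))
    eps_c_grid <- max(eps) + span * seq(0.01, 1.2, length.out = 60)
  }
  if (is.null(z_c_grid))
    z_c_grid <- seq(max(z_max) + 0.05, max(z_max) + 2.5, length.out = 50)

  best <- list(r2 = -Inf)
  for (zc in z_c_grid) {
    dz <- zc - z_max
    if (any(dz <= 0)) next
    ldz <- log(dz)
    tss <- sum((ldz - mean(ldz))^2)
    for (ec in eps_c_grid) {
      f <- stats::lm(ldz ~ log(ec - eps))
      r2 <- if (tss > 0) 1 - sum(stats::residuals(f)^2) / tss else 1
      if (r2 > best$r2)
        best <- list(r2 = r2, ec = ec, zc = zc,
                     theta = unname(stats::coef(f)[2]),
                     amp = exp(unname(stats::coef(f)[1])))
    }
  }
  if (!is.finite(best$r2)) stop("no candidate (eps_c, z_c) fits the data")
  boots <- if (n_boot <= 0) NA_real_ else replicate(n_boot, {
    idx <- sample.int(length(eps), replace = TRUE)
    if (length(unique(idx)) < 3) return(NA_real_)
    dz <- best$zc - z_max[idx]
    if (any(dz <= 0) || any(best$ec - eps[idx] <= 0)) return(NA_real_)
    unname(stats::coef(stats::lm(log(dz) ~ log(best$ec - eps[idx])))[2])
  })
  structure(list(critical = best$ec, exponent = best$theta, z_c = best$zc,
                 amplitude = best$amp,
                 se = stats::sd(boots, na.rm = TRUE),
                 r_squared = best$r2, n = length(eps)),
            class = "scaling_fit")
}

#' Fractal dimension from the hyperscaling relation
#'
#' Standard percolation hyperscaling links the cluster-mass distribution
#' exponent \eqn{\tau}, the spatial dimension \eqn{d} and the fractal
#' dimension: \eqn{\tau = d/d_f + 1}, i.e. \eqn{d_f = d/(\tau - 1)}.
#' With the gel-phase prediction \eqn{\tau = 5/2} in \eqn{d = 3} this gives
#' \eqn{d_f = 2}.
#'
#' @param tau cluster-mass distribution exponent (its magnitude), `> 1`.
#' @param d spatial dimension.
#' @return The fractal dimension \eqn{d_f}.
#' @export
hyperscaling_df <- function(tau, d = 3) {
  if (any(tau <= 1)) stop("hyperscaling requires tau > 1")
  d / (tau - 1)
}
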