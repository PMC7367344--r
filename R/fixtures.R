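#' Sample cluster sizes from a power law with exponential cutoff
#'
#' I.i.d. draws from the normalised discrete law
#' \eqn{P(k) \propto k^{-\tau} e^{-k/k_c}}, the stationary sol-phase
#' cluster-mass distribution shape, by inverse-CDF lookup on a precomputed
#' table.
#'
#' @param n number of draws.
#' @param tau power-law exponent (magnitude), `> 1`.
#' @param k_c exponential cutoff size.
#' @param k_max table truncation; default far beyond the cutoff.
#' @return Integer vector of sizes.
#' @export
sample_cluster_sizes <- function(n, tau = 1.5, k_c = 100,
                                 k_max = max(1000, ceiling(30 * k_c))) {
  stopifnot(tau > 1, k_c > 0, n >= 0)
  k <- seq_len(k_max)
  w <- exp(-tau * log(k) - k / k_c)
  cdf <- cumsum(w) / sum(w)
  findInterval(stats::runif(n), cdf) + 1L
}

# fractional Gaussian noise by circulant embedding (Davies-Harte);
# returns n increments with Hurst exponent H
.fgn <- function(n, H) {
  if (n == 0) return(numeric(0))
  if (n == 1) return(stats::rnorm(1))
  gam <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                              abs(k - 1)^(2 * H))
  m <- 2 * (n - 1)
  cvec <- gam(c(0:(n - 1), (n - 2):1))
  ev <- Re(stats::fft(cvec))
  ev[ev < 0] <- 0  # clip tiny negative eigenvalues from round-off
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  x <- Re(stats::fft(sqrt(ev / m) * z))
  x[seq_len(n)]
}

.fixture_cache <- new.env(parent = emptyenv())

# measured mass-radius slope for chains built at Hurst exponent H
.chain_slope <- function(H, sizes = c(16, 32, 64, 128, 256, 512),
                         reps = 6, bond = 1) {
  rg <- vapply(sizes, function(s) {
    mean(vapply(seq_len(reps), function(r) {
      p <- .fbm_chain(s, H, bond)
      sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
    }, numeric(1)))
  }, numeric(1))
  # slope of log N vs log Rg = measured fractal dimension
  unname(stats::coef(stats::lm(log(sizes) ~ log(rg)))[2])
}

.fbm_chain <- function(size, H, bond) {
  if (size == 1) return(matrix(0, 1, 3))
  if (H >= 0.995) {  # straight chain
    return(cbind(bond * (seq_len(size) - 1), 0, 0))
  }
  steps <- cbind(.fgn(size - 1, H), .fgn(size - 1, H), .fgn(size - 1, H))
  len <- sqrt(rowSums(steps^2))
  len[len == 0] <- 1
  steps <- bond * steps / len
  rbind(0, apply(steps, 2, cumsum))
}

# compact cluster: boustrophedon (serpentine) path through a cubic lattice;
# connected, all consecutive distances = bond, R_g ~ N^(1/3) exactly
.serpentine_chain <- function(size, bond) {
  if (size == 1) return(matrix(0, 1, 3))
  M <- ceiling(size^(1 / 3))
  coords <- matrix(0, size, 3)
  n <- 0L
  for (i in 0:(M - 1)) {
    jj <- if (i %% 2 == 0) 0:(M - 1) else (M - 1):0
    for (j in jj) {
      kk <- if ((i + j) %% 2 == 0) 0:(M - 1) else (M - 1):0
      for (k in kk) {
        n <- n + 1L
        coords[n, ] <- c(i, j, k)
        if (n == size) return(coords * bond)
      }
    }
  }
  coords * bond
}

#' Build a connected cluster with prescribed fractal dimension
#'
#' Grows a bonded chain whose step directions follow fractional Gaussian
#' noise with Hurst exponent \eqn{H \approx 1/d_f}, so that the mass-radius
#' relation obeys \eqn{\langle R_g(N)\rangle \propto N^{1/d_f}} over the
#' full size range (the construction is scale-free, with no crossover
#' length).  All consecutive neighbour distances equal the bond length and
#' connectivity is guaranteed.  Because normalising step lengths slightly
#' distorts the scaling, the Hurst exponent is calibrated once per target
#' \eqn{d_f} against the measured mass-radius slope and cached.
#'
#' @param size number of particles (>= 1).
#' @param d_f target fractal dimension, in (1, 3] (1 gives a straight
#'   chain).
#' @param bond bond length.
#' @param seed optional RNG seed for a reproducible cluster.
#' @return A `size` x 3 matrix of member coordinates (centred).
#' @export
build_cluster <- function(size, d_f, bond = 1, seed = NULL) {
  stopifnot(size >= 1)
  if (d_f < 1 || d_f > 3)
    stop("fractal dimension must lie in [1, 3] for a chain construction")
  if (!is.null(seed)) set.seed(seed)
  if (d_f > 2.6) {
    if (d_f < 2.95)
      warning("fractal dimensions in (2.6, 2.95) are not reachable by the ",
              "chain generator; building a compact (d_f = 3) cluster")
    p <- .serpentine_chain(size, bond)
  } else {
    H <- .calibrated_H(d_f)
    p <- .fbm_chain(size, H, bond)
  }
  sweep(p, 2, colMeans(p))
}

.calibrated_H <- function(d_f, tol = 0.03) {
  if (d_f <= 1.005) return(1)
  key <- sprintf("H_%.4f", d_f)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  H <- 1 / d_f
  old <- .Random.seed_save()
  set.seed(20113L)
  for (it in 1:4) {
    meas <- .chain_slope(H)
    if (abs(meas - d_f) < tol) break
    H <- min(0.99, max(0.05, H * meas / d_f))
  }
  .Random.seed_restore(old)
  .fixture_cache[[key]] <- H
  H
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assemble a particle frame with known cluster structure
#'
#' Samples cluster sizes from the power-law/cutoff law, builds each cluster
#' at the target fractal dimension, and places the clusters at
#' non-overlapping locations with inter-cluster gaps larger than twice the
#' bond length, so that the bond criterion recovers exactly the generator's
#' partition.  Returns both the frame and the ground truth.
#'
#' @param n_clusters number of clusters (or pass explicit `sizes`).
#' @param tau,k_c size-law parameters (see [sample_cluster_sizes()]).
#' @param d_f target fractal dimension of every cluster.
#' @param bond bond length.
#' @param sizes explicit cluster sizes overriding the sampler.
#' @param box box edge; default auto-sized to fit all clusters.
#' @param seed optional RNG seed.
#' @return List with `frame` (a `"particle_frame"`), `labels` (ground-truth
#'   cluster label per particle) and `sizes`.
#' @export
assemble_frame <- function(n_clusters = 100, tau = 1.5, k_c = 50, d_f = 2,
                           bond = 1, sizes = NULL, box = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sizes)) sizes <- sample_cluster_sizes(n_clusters, tau, k_c)
  n_clusters <- length(sizes)
  if (n_clusters == 0) {
    return(list(frame = particle_frame(matrix(0, 0, 3), box = if (is.null(box)) 1 else box),
                labels = integer(0), sizes = integer(0)))
  }
  clusters <- lapply(sizes, function(s) build_cluster(s, d_f, bond))
  ext <- vapply(clusters, function(p) max(0, max(apply(p, 2, function(v)
    diff(range(v))))), numeric(1))
  cell <- max(ext) + 3 * bond  # gap > 2 * bond between any two clusters
  ncell <- ceiling(n_clusters^(1 / 3))
  L <- ncell * cell
  if (!is.null(box)) {
    if (box < L) stop("box too small to place the clusters without contact; ",
                      "need at least ", signif(L, 4))
    L <- box
    ncell <- floor(L / cell)
    if (ncell^3 < n_clusters) stop("box too small for the cluster count")
  }
  slots <- utils::head(as.matrix(expand.grid(x = seq_len(ncell),
                                             y = seq_len(ncell),
                                             z = seq_len(ncell))),
                       n_clusters)
  slots <- (slots - 0.5) * cell
  pos <- do.call(rbind, lapply(seq_len(n_clusters), function(i) {
    # random rotation keeps the ensemble isotropic
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- .quat_rotation(q)
    sweep(clusters[[i]] %*% t(R), 2, slots[i, ], "+")
  }))
  labels <- rep(seq_len(n_clusters), sizes)
  frame <- particle_frame(pos, box = L, species = integer(nrow(pos)),
                          radii = rep(bond / 2, nrow(pos)),
                          mass = rep(1, nrow(pos)))
  list(frame = frame, labels = labels, sizes = as.integer(sizes))
}

.quat_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Scripted trajectory with known merge and split events
#'
#' Emits frames in which cluster memberships change exactly according to a
#' schedule of events, with coordinates teleported consistently (clusters
#' are rendered as bonded chains parked at well-separated anchors).  Ground
#' truth for event tracking and rate estimation.
#'
#' @param schedule data.frame with columns `time`, `kind`
#'   (`"merge"`/`"split"`), `a`, `b`: merge joins cluster ids `a` and `b`;
#'   split chips `b` particles off cluster `a` into a new cluster (ids grow
#'   consecutively).
#' @param sizes initial cluster sizes (cluster ids `1..length(sizes)`).
#' @param bond bond length (chain spacing).
#' @param frame_interval sampling interval; events must be separated by at
#'   least one interval for unambiguous tracking.
#' @param t_end final time; default just past the last event.
#' @return A `"gel_trajectory"` whose contact structure at cutoff
#'   `1.1 * bond` reproduces the scheduled cluster memberships.
#' @export
scripted_trajectory <- function(schedule, sizes, bond = 1,
                                frame_interval = 1, t_end = NULL) {
  stopifnot(all(sizes >= 1))
  if (nrow(schedule) > 0) {
    schedule <- schedule[order(schedule$time), , drop = FALSE]
    stopifnot(all(schedule$kind %in% c("merge", "split")))
  }
  if (is.null(t_end))
    t_end <- if (nrow(schedule) > 0) max(schedule$time) + frame_interval else
      frame_interval

  n <- sum(sizes)
  members <- split(seq_len(n), rep(seq_along(sizes), sizes))
  names(members) <- as.character(seq_along(sizes))
  next_id <- length(sizes) + 1L
  # peak number of concurrent clusters sets the anchor-slot count
  delta <- ifelse(schedule$kind == "split", 1L, -1L)
  max_slots <- length(sizes) +
    (if (length(delta)) max(0L, max(cumsum(delta))) else 0L) + 1L
  slot_of <- seq_along(sizes)  # cluster id -> anchor slot
  names(slot_of) <- names(members)
  free_slots <- setdiff(seq_len(max_slots), slot_of)

  row_sep <- 3 * bond
  L <- max((n + 2) * bond, (max_slots + 2) * row_sep)

  render <- function(time) {
    pos <- matrix(0, n, 3)
    for (id in names(members)) {
      mem <- members[[id]]
      y <- slot_of[[id]] * row_sep
      pos[mem, ] <- cbind(bond * (seq_along(mem) - 1) + bond, y, L / 2)
    }
    particle_frame(pos, box = L, time = time, species = integer(n),
                   radii = rep(bond / 2, n), mass = rep(1, n))
  }

  frame_times <- seq(0, t_end, by = frame_interval)
  frames <- list()
  ei <- 1L
  for (ft in frame_times) {
    while (ei <= nrow(schedule) && schedule$time[ei] <= ft) {
      ev <- schedule[ei, ]
      ia <- as.character(ev$a); ib <- as.character(ev$b)
      if (ev$kind == "merge") {
        if (is.null(members[[ia]]) || is.null(members[[ib]]))
          stop("merge references a cluster that no longer exists (event ",
               ei, ")")
        members[[ia]] <- c(members[[ia]], members[[ib]])
        free_slots <- c(free_slots, slot_of[[ib]])
        members[[ib]] <- NULL
        slot_of <- slot_of[names(slot_of) != ib]
      } else {
        if (is.null(members[[ia]]))
          stop("split references a cluster that no longer exists (event ",
               ei, ")")
        chip <- ev$b
        if (chip >= length(members[[ia]]) || chip < 1)
          stop("split size violates mass conservation (event ", ei, ")")
        mem <- members[[ia]]
        members[[ia]] <- mem[seq_len(length(mem) - chip)]
        newid <- as.character(next_id)
        members[[newid]] <- mem[(length(mem) - chip + 1):length(mem)]
        slot_of[[newid]] <- free_slots[1]
        free_slots <- free_slots[-1]
        next_id <- next_id + 1L
      }
      ei <- ei + 1L
    }
    frames[[length(frames) + 1L]] <- render(ft)
  }
  structure(list(frames = frames, config = NULL, log = NULL),
            class = "gel_trajectory")
}

#' Poisson split/re-merge schedule
#'
#' Each of `n_clusters` independent clusters of size `size` chips off one
#' particle at Poisson rate `rate`; every chip is re-merged one frame
#' interval later (a renewal process per cluster).  Used to test that the
#' rate estimators recover a known event rate, and — with enough clusters
#' that concentrations factorise — that matched forward/backward event
#' schedules give detailed-balance flux ratios of 1.
#'
#' @param rate Poisson split rate per cluster (per \eqn{t_s}).
#' @param size cluster size.
#' @param t_end schedule duration.
#' @param frame_interval sampling interval of the intended trajectory.
#' @param n_clusters number of independent clusters.
#' @param seed optional RNG seed.
#' @return List with `schedule` (data.frame for [scripted_trajectory()])
#'   and `sizes` (initial cluster sizes).
#' @export
poisson_churn_schedule <- function(rate, size, t_end, frame_interval = 1,
                                   n_clusters = 1, seed = NULL) {
  stopifnot(rate > 0, size >= 2, n_clusters >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cl in seq_len(n_clusters)) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, rate)
      if (t + 2 * frame_interval > t_end) break
      rows[[length(rows) + 1]] <- data.frame(time = t, kind = "split",
                                             a = cl, b = 1)
      rows[[length(rows) + 1]] <- data.frame(time = t + frame_interval,
                                             kind = "merge", a = cl, b = NA)
      t <- t + frame_interval  # chip is outstanding until here
    }
  }
  sched <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), kind = character(0), a = numeric(0),
               b = numeric(0))
  if (nrow(sched) > 0) {
    sched <- sched[order(sched$time), , drop = FALSE]
    # ids of chipped singletons are assigned in time order by the renderer;
    # each merge rejoins its own cluster's latest chip
    next_id <- n_clusters + 1
    chip_of <- integer(n_clusters)
    for (r in seq_len(nrow(sched))) {
      if (sched$kind[r] == "split") {
        chip_of[sched$a[r]] <- next_id
        next_id <- next_id + 1
      } else {
        sched$b[r] <- chip_of[sched$a[r]]
      }
    }
  }
  list(schedule = sched, sizes = rep(size, n_clusters))
}
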