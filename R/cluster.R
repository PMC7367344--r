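#' Bond criterion for contact detection
#'
#' Simulation mode bonds particles whose centres lie within the inflection
#' point of the pair potential (scaled per species pair with the contact
#' distance); experiment mode bonds particle centroids closer than a fixed
#' distance `d0` (open boundaries).
#'
#' @param mode `"simulation"` or `"experiment"`.
#' @param potential pair potential (simulation mode); defaults to the
#'   Mie(30, 20) reference.
#' @param cutoff explicit bond distance overriding the inflection radius.
#' @param d0 experimental bond distance (defaults to `2.6 * r`).
#' @param r nominal particle radius in experiment mode.
#' @return A list of class `"bond_criterion"`.
#' @export
bond_criterion <- function(mode = c("simulation", "experiment"),
                           potential = NULL, cutoff = NULL, d0 = NULL,
                           r = 1) {
  mode <- match.arg(mode)
  if (mode == "simulation") {
    if (is.null(cutoff)) {
      if (is.null(potential)) potential <- mie_potential()
      cutoff <- inflection_radius(potential)
    }
  } else {
    if (is.null(d0)) d0 <- 2.6 * r
    cutoff <- d0
  }
  structure(list(mode = mode, cutoff = cutoff, r = r),
            class = "bond_criterion")
}

#' Directly contacting particle pairs
#'
#' All and only pairs whose separation satisfies the bond criterion, under
#' periodic minimum image (simulation) or open boundaries (experiment point
#' clouds).  For a binary mixture the bond distance is scaled per species
#' pair with the contact distance \eqn{\sigma_{ij}}.
#'
#' @param frame a `"particle_frame"`, or a matrix / data.frame of positions
#'   in experiment mode.
#' @param criterion a [bond_criterion()] (or a bare numeric cutoff, taken as
#'   simulation mode).
#' @param size_ratio contact-distance ratio used for per-pair scaling.
#' @return A `"contact_graph"`: data.frame of bonded pairs (`i`, `j`,
#'   `dist`, image offsets) with attributes `n_particles`, `box`,
#'   `criterion`, `positions`.
#' @export
contact_pairs <- function(frame, criterion = bond_criterion(),
                          size_ratio = 1.1) {
  if (is.numeric(criterion))
    criterion <- structure(list(mode = "simulation", cutoff = criterion),
                           class = "bond_criterion")
  if (!inherits(criterion, "bond_criterion"))
    stop("unknown bond criterion")
  if (criterion$mode == "simulation") {
    stopifnot(inherits(frame, "particle_frame"))
    scale <- c(1, 0.5 * (1 + size_ratio), size_ratio)
    maxcut <- criterion$cutoff * max(scale)
    pr <- neighbor_pairs(frame, maxcut)
    type <- frame$species[pr$i] + frame$species[pr$j] + 1L
    keep <- pr$dist < criterion$cutoff * scale[type]
    pr <- pr[keep, , drop = FALSE]
    structure(pr, n_particles = nrow(frame$positions), box = frame$box,
              periodic = TRUE, criterion = criterion,
              positions = frame$positions,
              class = c("contact_graph", class(pr)))
  } else {
    pos <- if (inherits(frame, "particle_frame")) frame$positions else
      as.matrix(frame[, 1:3, drop = FALSE])
    pr <- .open_pairs(pos, criterion$cutoff)
    structure(pr, n_particles = nrow(pos), box = NA_real_, periodic = FALSE,
              criterion = criterion, positions = pos,
              class = c("contact_graph", class(pr)))
  }
}

# open-boundary pair search: reuse the periodic cell list inside a padded box
.open_pairs <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0),
                      off_x = numeric(0), off_y = numeric(0),
                      off_z = numeric(0)))
  lo <- apply(pos, 2, min)
  shifted <- sweep(pos, 2, lo) + 1.5 * cutoff
  L <- max(apply(shifted, 2, max)) + 1.5 * cutoff
  L <- max(L, 2.5 * cutoff)
  as.data.frame(neighbor_pairs_cpp(shifted, L, cutoff))
}

#' Connected clusters of bonded particles
#'
#' Partitions particles into connected components of the contact graph.
#' Labels are deterministic: components are numbered in order of their
#' smallest particle index.  Positions are unwrapped across periodic images
#' by walking the bond graph, which also detects spanning (percolating)
#' clusters: a cluster that connects to its own periodic image along any
#' axis closes a bond loop with a non-zero net image offset.
#'
#' @param graph a `"contact_graph"` from [contact_pairs()].
#' @return A `"cluster_set"`: list with `labels` (per particle), `sizes`,
#'   `rg` (radius of gyration per cluster, on unwrapped coordinates),
#'   `spanning` (flag per cluster), `unwrapped` (positions), `n_particles`.
#' @export
cluster_labels <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  n <- attr(graph, "n_particles")
  pos <- attr(graph, "positions")
  periodic <- isTRUE(attr(graph, "periodic"))
  box <- attr(graph, "box")

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(graph) > 0)
    g <- igraph::add_edges(g, rbind(graph$i, graph$j))
  comp <- igraph::components(g)
  memb <- comp$membership
  # deterministic labels: order components by smallest member index
  first <- tapply(seq_len(n), memb, min)
  ord <- order(first)
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  labels <- relabel[memb]

  unwrap <- .unwrap_clusters(labels, graph, pos, box, periodic)

  sizes <- tabulate(labels)
  rg <- vapply(seq_along(sizes), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) == 1) return(0)
    p <- unwrap$positions[idx, , drop = FALSE]
    sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
  }, numeric(1))

  structure(list(labels = labels, sizes = sizes, rg = rg,
                 spanning = unwrap$spanning, unwrapped = unwrap$positions,
                 n_particles = n, box = box, periodic = periodic),
            class = "cluster_set")
}

# BFS over the bond graph, assigning unwrapped coordinates; a revisited
# vertex whose assigned coordinate disagrees with the bond displacement marks
# a cluster connected to its own periodic image (spanning).
.unwrap_clusters <- function(labels, graph, pos, box, periodic) {
  n <- length(labels)
  upos <- pos
  spanning <- rep(FALSE, max(labels))
  if (!periodic || nrow(graph) == 0)
    return(list(positions = upos, spanning = spanning))

  m <- nrow(graph)
  ef <- c(graph$i, graph$j)
  et <- c(graph$j, graph$i)
  adj_ord <- order(ef)
  ef <- ef[adj_ord]; et <- et[adj_ord]
  # displacement of 'to' relative to 'from' under minimum image
  dvec <- pos[et, , drop = FALSE] - pos[ef, , drop = FALSE]
  dvec <- dvec - box * round(dvec / box)
  ptr <- c(0, cumsum(tabulate(ef, n)))  # CSR-style index

  visited <- rep(FALSE, n)
  queue <- integer(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue[1] <- root
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nk <- ptr[v + 1] - ptr[v]
      if (nk == 0) next
      for (k in seq.int(ptr[v] + 1, length.out = nk)) {
        w <- et[k]
        cand <- upos[v, ] + dvec[k, ]
        if (!visited[w]) {
          visited[w] <- TRUE
          upos[w, ] <- cand
          tail <- tail + 1L
          queue[tail] <- w
        } else if (any(abs(cand - upos[w, ]) > 1e-6 * box)) {
          spanning[labels[v]] <- TRUE
        }
      }
    }
  }
  list(positions = upos, spanning = spanning)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d particles in %d clusters (largest %d%s)\n",
              x$n_particles, length(x$sizes), max(x$sizes),
              if (any(x$spanning)) ", spanning" else ""))
  invisible(x)
}

#' Mean coordination number
#'
#' Average number of bonded neighbours per particle,
#' \eqn{z = 2 n_{bonds} / N}: the order parameter of the gelation
#' transition.
#'
#' @param graph a `"contact_graph"`.
#' @return The mean coordination number.
#' @export
mean_coordination <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  2 * nrow(graph) / attr(graph, "n_particles")
}

#' Radius of gyration of a cluster
#'
#' \eqn{R_g^2 = \langle |r_i - r_{cm}|^2 \rangle} over the member positions.
#' In a periodic box the members are first unwrapped by walking the bond
#' graph (pass `graph`); a spanning cluster has no consistent unwrapping and
#' its \eqn{R_g}, computed on the unwrapped spanning tree, is reported with
#' a warning.
#'
#' @param positions member coordinates (N x 3), or a `"cluster_set"` plus
#'   cluster index via `cluster`.
#' @param box periodic box edge (NULL for open boundaries).
#' @param graph optional `"contact_graph"` restricted to the members, used
#'   for unwrapping; member positions must be rows of the graph's frame.
#' @param members particle indices of the cluster within `graph`.
#' @return The radius of gyration.
#' @export
gyration_radius <- function(positions, box = NULL, graph = NULL,
                            members = NULL) {
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "contact_graph"))
    cs <- cluster_labels(graph)
    if (is.null(members)) {
      labs <- unique(cs$labels)
      if (length(labs) > 1)
        stop("graph is disconnected; pass `members` to select one cluster")
      members <- which(cs$labels == labs[1])
    }
    lab <- unique(cs$labels[members])
    if (length(lab) != 1)
      stop("members do not form a single connected cluster")
    if (cs$spanning[lab])
      warning("cluster spans the periodic box; R_g computed on the unwrapped tree")
    p <- cs$unwrapped[members, , drop = FALSE]
  } else {
    p <- as.matrix(positions)
  }
  if (nrow(p) == 1) return(0)
  sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
}

#' Correlation length of the cluster population
#'
#' \deqn{\xi^2 = \frac{2\sum_i R_{gi}^2 N_i^2}{\sum_i N_i^2},}
#' the cluster-size-weighted length scale of connected particles.
#'
#' @param clusters a `"cluster_set"`.
#' @param include_largest include the largest cluster in the sums (set to
#'   FALSE after percolation, when the spanning cluster dominates).
#' @return The correlation length (0 when all clusters are singletons).
#' @export
correlation_length <- function(clusters, include_largest = TRUE) {
  stopifnot(inherits(clusters, "cluster_set"))
  sizes <- clusters$sizes
  rg <- clusters$rg
  if (!include_largest && length(sizes) > 1) {
    drop <- which.max(sizes)
    sizes <- sizes[-drop]
    rg <- rg[-drop]
  }
  if (length(sizes) == 0 || sum(sizes^2) == 0) return(0)
  sqrt(2 * sum(rg^2 * sizes^2) / sum(sizes^2))
}

#' Cluster-mass histogram
#'
#' Counts of clusters per size, optionally excluding the largest cluster
#' (the standard choice after percolation, where the spanning cluster is
#' removed from the finite-cluster population) and optionally aggregated in
#' logarithmic bins normalised per unit bin width.
#'
#' @param clusters a `"cluster_set"`.
#' @param log_binned aggregate into logarithmic bins.
#' @param bins_per_decade resolution of the logarithmic binning.
#' @param drop_largest remove the single largest cluster before counting.
#' @param volume if given, counts are converted to number densities.
#' @return A data.frame with columns `k` (size, or bin centre), `count` and
#'   `density` (count per unit size per unit volume).
#' @export
mass_histogram <- function(clusters, log_binned = FALSE,
                           bins_per_decade = 5, drop_largest = FALSE,
                           volume = NULL) {
  stopifnot(inherits(clusters, "cluster_set"), length(clusters$sizes) > 0)
  sizes <- clusters$sizes
  if (drop_largest && length(sizes) > 1) sizes <- sizes[-which.max(sizes)]
  vol <- if (is.null(volume)) 1 else volume
  if (!log_binned) {
    tab <- table(sizes)
    k <- as.integer(names(tab))
    count <- as.integer(tab)
    data.frame(k = k, count = count, density = count / vol)
  } else {
    edges <- 10^(seq(0, ceiling(log10(max(sizes))) + 1 / bins_per_decade,
                     by = 1 / bins_per_decade))
    edges <- unique(c(1, edges[edges > 1]))
    bin <- findInterval(sizes, edges, rightmost.closed = FALSE)
    width <- pmax(1, diff(c(edges, 2 * edges[length(edges)])))
    cnt <- tabulate(bin, nbins = length(edges))
    keep <- cnt > 0
    data.frame(k = sqrt(edges * c(edges[-1], 2 * edges[length(edges)]))[keep],
               count = cnt[keep],
               density = (cnt / (width * vol))[keep])
  }
}

#' Largest-cluster fractions and percolation flag
#'
#' Fractions of all particles in the two largest clusters, and whether any
#' cluster percolates (connects to its own periodic image along any axis;
#' for open boxes, extends across the full box edge).
#'
#' @param clusters a `"cluster_set"`.
#' @param box_extent open-boundary box edge used for the spanning test when
#'   the frame is not periodic.
#' @return List with `f_z`, `second_fraction`, `percolating`.
#' @export
largest_clusters <- function(clusters, box_extent = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  fr <- sort(clusters$sizes, decreasing = TRUE) / clusters$n_particles
  perc <- any(clusters$spanning)
  if (!clusters$periodic) {
    ext <- if (is.null(box_extent)) clusters$box else box_extent
    if (!is.null(ext) && is.finite(ext)) {
      perc <- any(vapply(seq_along(clusters$sizes), function(cl) {
        p <- clusters$unwrapped[clusters$labels == cl, , drop = FALSE]
        any(apply(p, 2, function(v) diff(range(v))) >= ext)
      }, logical(1)))
    }
  }
  list(f_z = fr[1],
       second_fraction = if (length(fr) > 1) fr[2] else 0,
       percolating = perc)
}

#' Fractal dimension from the mass-radius relation
#'
#' Least-squares slope of \eqn{\log N_i} versus \eqn{\log R_{gi}} over a
#' cluster-size window: \eqn{N \propto R_g^{d_f}} defines the fractal
#' dimension \eqn{d_f}.  Standard errors are obtained by bootstrap over
#' clusters.
#'
#' @param clusters a `"cluster_set"`, or a data.frame with columns `size`
#'   and `rg`.
#' @param size_window inclusive size range of clusters entering the fit;
#'   default `c(5, 0.1 * N)` avoids singleton noise and the spanning
#'   cluster.
#' @param n_boot bootstrap replicates for the standard error.
#' @param min_clusters minimum number of clusters of size >= 3 required.
#' @return A `"scaling_fit"` with `exponent` (\eqn{d_f}), `amplitude`,
#'   `se`, `window`, `n`.
#' @export
fractal_dimension <- function(clusters, size_window = NULL, n_boot = 200,
                              min_clusters = 10) {
  if (inherits(clusters, "cluster_set")) {
    df <- data.frame(size = clusters$sizes, rg = clusters$rg)
    ntot <- clusters$n_particles
  } else {
    df <- as.data.frame(clusters)
    ntot <- sum(df$size)
  }
  if (is.null(size_window)) size_window <- c(5, max(5, 0.1 * ntot))
  sel <- df$size >= size_window[1] & df$size <= size_window[2] & df$rg > 0
  if (sum(sel & df$size >= 3) < min_clusters)
    stop("too few clusters in the size window for a fractal-dimension fit")
  x <- log(df$rg[sel])
  y <- log(df$size[sel])
  fit <- stats::lm(y ~ x)
  boots <- if (n_boot <= 0) NA_real_ else replicate(n_boot, {
    idx <- sample.int(length(x), replace = TRUE)
    stats::coef(stats::lm(y[idx] ~ x[idx]))[2]
  })
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 amplitude = exp(unname(stats::coef(fit)[1])),
                 se = stats::sd(boots), window = size_window,
                 n = sum(sel), r_squared = summary(fit)$r.squared),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("scaling_fit:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) <= 2)
      cat(sprintf("  %-12s %s\n", nm, paste(signif(v, 5), collapse = " ")))
  }
  invisible(x)
}

#' Experimental double-threshold clustering
#'
#' Mirrors the analysis of particle-tracking data: bonds (used for the
#' coordination number) are pairs closer than `d0 = 2.6 r`, while grouping
#' into clusters uses the looser threshold `dc = 3.5 r`.
#'
#' @param points matrix or data.frame of coordinates (columns x, y, z).
#' @param r nominal particle radius.
#' @param d0 bond distance.
#' @param dc clustering distance.
#' @return A `"cluster_set"` grouped at `dc`, with the bond graph at `d0`
#'   attached as attribute `"bonds"`.
#' @export
experiment_grouping <- function(points, r = 1, d0 = 2.6 * r, dc = 3.5 * r) {
  pos <- as.matrix(as.data.frame(points)[, 1:3])
  crit_bond <- bond_criterion("experiment", d0 = d0, r = r)
  crit_group <- bond_criterion("experiment", d0 = dc, r = r)
  bonds <- contact_pairs(pos, crit_bond)
  groups <- contact_pairs(pos, crit_group)
  cs <- cluster_labels(groups)
  attr(cs, "bonds") <- bonds
  cs
}

#' Per-frame gelation order parameters
#'
#' Computes, from one frame, the mean coordination number `z`, the fraction
#' of particles in the largest cluster `f_z`, the second-largest fraction,
#' the correlation length `xi` and the percolation flag.  After percolation
#' the spanning (largest) cluster is excluded from `xi` by default.
#'
#' @param frame a `"particle_frame"`.
#' @param criterion a [bond_criterion()].
#' @param exclude_spanning_xi exclude the largest cluster from `xi` once the
#'   frame percolates.
#' @param size_ratio species contact-distance ratio.
#' @return One-row data.frame.
#' @export
frame_metrics <- function(frame, criterion = bond_criterion(),
                          exclude_spanning_xi = TRUE, size_ratio = 1.1) {
  graph <- contact_pairs(frame, criterion, size_ratio = size_ratio)
  cs <- cluster_labels(graph)
  lc <- largest_clusters(cs)
  include <- !(exclude_spanning_xi && lc$percolating)
  data.frame(time = frame$time,
             z = mean_coordination(graph),
             f_z = lc$f_z,
             second_fraction = lc$second_fraction,
             xi = correlation_length(cs, include_largest = include),
             percolating = lc$percolating,
             n_clusters = length(cs$sizes))
}

#' @rdname frame_metrics
#' @param traj a `"gel_trajectory"`.
#' @export
trajectory_metrics <- function(traj, criterion = bond_criterion(),
                               exclude_spanning_xi = TRUE,
                               size_ratio = 1.1) {
  stopifnot(inherits(traj, "gel_trajectory"))
  do.call(rbind, lapply(traj$frames, frame_metrics, criterion = criterion,
                        exclude_spanning_xi = exclude_spanning_xi,
                        size_ratio = size_ratio))
}
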