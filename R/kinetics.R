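#' Track cluster merge and split events along a trajectory
#'
#' Matches clusters across consecutive (finely sampled) frames by particle
#' identity.  A cluster whose members came from two prior clusters of sizes
#' i and j logs a merge \eqn{i + j \to i+j}; a prior cluster whose members
#' separate into two logs a split \eqn{k \to i + j}.  Compound transitions
#' (more than two clusters involved between consecutive frames) are
#' decomposed greedily into binary events ordered by largest shared
#' membership and flagged `ambiguous`; a warning is issued when more than
#' 1\% of transitions are ambiguous, indicating the frame spacing is too
#' coarse.
#'
#' @param traj a `"gel_trajectory"` (or list of `"particle_frame"`s).
#' @param criterion a [bond_criterion()].
#' @param size_ratio species contact-distance ratio for per-pair bond
#'   scaling.
#' @return A `"cluster_event_log"`: data.frame with columns `time`, `kind`
#'   (`"merge"`/`"split"`), `i`, `j`, `k` (`k = i + j`), `ambiguous`, and
#'   attributes `counts` (per-frame cluster-size counts), `times`,
#'   `volume`, `n_particles`.
#' @export
track_events <- function(traj, criterion = bond_criterion(),
                         size_ratio = 1.1) {
  frames <- if (inherits(traj, "gel_trajectory")) traj$frames else traj
  stopifnot(length(frames) >= 1)
  n <- nrow(frames[[1]]$positions)
  labs <- lapply(frames, function(f) {
    if (nrow(f$positions) != n)
      stop("inconsistent particle counts between frames")
    cluster_labels(contact_pairs(f, criterion, size_ratio = size_ratio))$labels
  })
  times <- vapply(frames, `[[`, numeric(1), "time")

  events <- list()
  for (t in seq_len(length(frames) - 1)) {
    ev <- .transition_events(labs[[t]], labs[[t + 1]], times[t + 1])
    if (nrow(ev) > 0) events[[length(events) + 1]] <- ev
  }
  log <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), kind = character(0), i = integer(0),
               j = integer(0), k = integer(0), ambiguous = logical(0))
  n_trans <- max(1L, length(frames) - 1L)
  if (sum(log$ambiguous) / n_trans > 0.01)
    warning("more than 1% of frame transitions contain compound events; ",
            "decrease the frame interval")
  counts <- lapply(labs, function(l) tabulate(tabulate(l)))
  structure(log, counts = counts, times = times,
            volume = if (!is.null(frames[[1]]$box) && is.finite(frames[[1]]$box))
              frames[[1]]$box^3 else NA_real_,
            n_particles = n,
            class = c("cluster_event_log", class(log)))
}

# events between two labelings (vectors of cluster ids per particle)
.transition_events <- function(prev, cur, time) {
  key <- paste(prev, cur)
  ov <- unique(data.frame(p = prev, c = cur, stringsAsFactors = FALSE))
  psz <- tabulate(prev)
  csz <- tabulate(cur)

  # groups of clusters linked by shared members (bipartite components)
  np <- max(prev)
  g <- igraph::make_empty_graph(np + max(cur), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ov$p, np + ov$c))
  comp <- igraph::components(g)$membership

  out <- list()
  for (grp in unique(comp[ov$p])) {
    pids <- unique(ov$p[comp[ov$p] == grp])
    cids <- unique(ov$c[comp[np + ov$c] == grp])
    p <- length(pids); q <- length(cids)
    if (p == 1 && q == 1) next
    amb <- (p > 2) || (q > 2) || (p > 1 && q > 1)
    if (q == 1) {  # pure merge(s): p prior clusters coalesced
      s <- sort(psz[pids], decreasing = TRUE)
      acc <- s[1]
      for (x in s[-1]) {
        out[[length(out) + 1]] <- data.frame(
          time = time, kind = "merge", i = acc, j = x, k = acc + x,
          ambiguous = amb)
        acc <- acc + x
      }
    } else if (p == 1) {  # pure split(s): chip off smallest first
      s <- sort(csz[cids])
      rest <- sum(s)
      for (x in s[-length(s)]) {
        out[[length(out) + 1]] <- data.frame(
          time = time, kind = "split", i = rest - x, j = x, k = rest,
          ambiguous = amb)
        rest <- rest - x
      }
    } else {
      # compound: match each current cluster to the prior cluster sharing
      # the most members (its continuation); leftovers are merges/splits
      shared <- table(factor(prev, levels = pids), factor(cur, levels = cids))
      cont <- apply(shared, 2, which.max)  # row index per current cluster
      # prior clusters absorbed into a current cluster beyond its continuation
      for (ci in seq_len(q)) {
        srcs <- which(shared[, ci] > 0)
        main <- cont[ci]
        extra <- setdiff(srcs, main)
        acc <- psz[pids[main]]
        for (e in extra) {
          # only count as merge if that prior cluster went mostly here
          if (which.max(shared[e, ]) == ci) {
            x <- psz[pids[e]]
            out[[length(out) + 1]] <- data.frame(
              time = time, kind = "merge", i = acc, j = x, k = acc + x,
              ambiguous = TRUE)
            acc <- acc + x
          }
        }
      }
      for (pi in seq_len(p)) {
        dests <- which(shared[pi, ] > 0 & cont == pi)
        if (length(dests) >= 2) {
          s <- sort(csz[cids[dests]])
          rest <- sum(s)
          for (x in s[-length(s)]) {
            out[[length(out) + 1]] <- data.frame(
              time = time, kind = "split", i = rest - x, j = x, k = rest,
              ambiguous = TRUE)
            rest <- rest - x
          }
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(time = numeric(0), kind = character(0), i = integer(0),
               j = integer(0), k = integer(0), ambiguous = logical(0))
}

#' Association and dissociation rate constants
#'
#' Turns an event log into the rate constants of the kinetic master
#' equation.  The dissociation constant is a per-cluster event rate,
#' \deqn{K^-_{ij} = \frac{\#\{k \to i + j\}}{\int n_k\,dt},\qquad k = i+j,}
#' (units \eqn{t_s^{-1}}); the association constant is a second-order rate,
#' \deqn{K^+_{ij} = \frac{\#\{i + j \to i+j\}}{V \int c_i c_j\,dt},}
#' with concentrations \eqn{c = n/V} in \eqn{r_a^{-3}} (units
#' \eqn{r_a^3 t_s^{-1}}).  Classes with zero exposure are absent, not zero.
#'
#' @param log a `"cluster_event_log"` from [track_events()].
#' @param volume simulation volume; default from the log attributes.
#' @return A `"rate_table"`: data.frame with `direction`, `i`, `j`,
#'   `events`, `exposure`, `rate`.  The attribute `"normalization"`
#'   documents the conventions above.
#' @export
rate_constants <- function(log, volume = NULL) {
  stopifnot(inherits(log, "cluster_event_log"))
  counts <- attr(log, "counts")
  times <- attr(log, "times")
  if (is.null(volume)) volume <- attr(log, "volume")
  stopifnot(is.finite(volume), length(times) >= 2)
  dt <- diff(times)
  kmax <- max(vapply(counts, length, integer(1)))
  nk <- vapply(counts, function(x) c(x, rep(0, kmax - length(x))),
               numeric(kmax))  # kmax x nframes
  if (is.null(dim(nk))) nk <- matrix(nk, nrow = kmax)
  # left-endpoint time integral of per-size counts over each interval
  Tk <- as.vector(nk[, -ncol(nk), drop = FALSE] %*% dt)

  canon <- function(i, j) cbind(pmax(i, j), pmin(i, j))
  out <- list()

  sp <- log[log$kind == "split", , drop = FALSE]
  if (nrow(sp) > 0) {
    ij <- canon(sp$i, sp$j)
    tab <- stats::aggregate(list(events = rep(1, nrow(sp))),
                            by = list(i = ij[, 1], j = ij[, 2]), FUN = sum)
    kk <- tab$i + tab$j
    # compound decomposition can reference intermediate sizes never observed
    # in a frame; their observation time is zero and the class is absent
    tab$exposure <- ifelse(kk <= length(Tk), Tk[pmin(kk, length(Tk))], 0)
    tab <- tab[!is.na(tab$exposure) & tab$exposure > 0, , drop = FALSE]
    if (nrow(tab) > 0)
      out[[length(out) + 1]] <- data.frame(direction = "dissociation", tab,
                                           rate = tab$events / tab$exposure)
  }
  mg <- log[log$kind == "merge", , drop = FALSE]
  if (nrow(mg) > 0) {
    ij <- canon(mg$i, mg$j)
    tab <- stats::aggregate(list(events = rep(1, nrow(mg))),
                            by = list(i = ij[, 1], j = ij[, 2]), FUN = sum)
    # exposure: V * int c_i c_j dt = (1/V) * int n_i n_j dt
    tab$exposure <- vapply(seq_len(nrow(tab)), function(r) {
      ii <- tab$i[r]; jj <- tab$j[r]
      if (ii > kmax || jj > kmax) return(0)
      sum(nk[ii, -ncol(nk)] * nk[jj, -ncol(nk)] * dt) / volume
    }, numeric(1))
    tab <- tab[tab$exposure > 0, , drop = FALSE]
    if (nrow(tab) > 0)
      out[[length(out) + 1]] <- data.frame(direction = "association", tab,
                                           rate = tab$events / tab$exposure)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(direction = character(0), i = integer(0), j = integer(0),
               events = numeric(0), exposure = numeric(0), rate = numeric(0))
  structure(res, volume = volume, total_time = sum(dt), size_exposure = Tk,
            normalization = paste(
              "dissociation: events per cluster of size k=i+j per t_s;",
              "association: events per (V int c_i c_j dt), c in r_a^-3"),
            class = c("rate_table", class(res)))
}

#' Size-classed event rates
#'
#' Aggregates the rate table by the size of the cluster taking part in the
#' event, the way reversible-aggregation kinetics are reported.  The
#' dissociation rate of size-k clusters is the j-average of the per-class
#' rate constants \eqn{K^-_{kj}} over the co-fragment size j (units
#' \eqn{t_s^{-1}}): single-particle break-off is `k = 1`, whole-cluster
#' detachment of larger fragments becomes rapidly rarer.  The association
#' rate of size-k clusters is reported in two normalisations: `rate`, the
#' per-cluster event rate \eqn{\#/\int n_k\,dt} (units \eqn{t_s^{-1}},
#' commensurable with the dissociation rate), and `rate_per_volume`, the
#' bulk event rate \eqn{\#/(V T)} (units \eqn{t_s^{-1} r_a^{-3}}).
#'
#' @param rates a `"rate_table"` (see [rate_constants()]).
#' @return A data.frame with `k`, `direction`, `events`, `rate`,
#'   `rate_per_volume` (NA for dissociation).
#' @export
rates_by_size <- function(rates) {
  stopifnot(inherits(rates, "rate_table"))
  V <- attr(rates, "volume")
  Ttot <- attr(rates, "total_time")
  Tk <- attr(rates, "size_exposure")
  out <- list()
  ds <- rates[rates$direction == "dissociation", , drop = FALSE]
  if (nrow(ds) > 0) {
    for (kk in sort(unique(c(ds$i, ds$j)))) {
      sel <- ds$i == kk | ds$j == kk
      out[[length(out) + 1]] <- data.frame(
        k = kk, direction = "dissociation", events = sum(ds$events[sel]),
        rate = mean(ds$rate[sel]), rate_per_volume = NA_real_)
    }
  }
  as_ <- rates[rates$direction == "association", , drop = FALSE]
  if (nrow(as_) > 0) {
    for (kk in sort(unique(c(as_$i, as_$j)))) {
      sel <- as_$i == kk | as_$j == kk
      ev <- sum(as_$events[sel])
      expo <- if (!is.null(Tk) && kk <= length(Tk)) Tk[kk] else NA_real_
      out[[length(out) + 1]] <- data.frame(
        k = kk, direction = "association", events = ev,
        rate = if (is.finite(expo) && expo > 0) ev / expo else NA_real_,
        rate_per_volume = ev / (V * Ttot))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(k = integer(0), direction = character(0),
               events = numeric(0), rate = numeric(0),
               rate_per_volume = numeric(0))
}

#' Detailed-balance flux ratios
#'
#' Ratio of the forward (association) flux \eqn{K^+_{ij} c_i c_j} to the
#' reverse (dissociation) flux \eqn{K^-_{ij} c_{i+j}} for every class with
#' both directions observed.  Detailed balance holds iff the ratio is 1;
#' in the gelation regime association fluxes exceed dissociation fluxes
#' for multi-particle classes.
#'
#' @param rates a `"rate_table"`.
#' @param concentrations numeric vector, `concentrations[k]` = mean number
#'   density of size-k clusters (units \eqn{r_a^{-3}}).
#' @return Data.frame with `i`, `j`, `forward`, `reverse`, `ratio`
#'   (`Inf` with `reverse_events = 0` metadata when no reverse events were
#'   seen).
#' @export
balance_ratio <- function(rates, concentrations) {
  stopifnot(inherits(rates, "rate_table"))
  as_ <- rates[rates$direction == "association", , drop = FALSE]
  ds <- rates[rates$direction == "dissociation", , drop = FALSE]
  if (nrow(as_) == 0) stop("no association classes observed")
  ck <- function(k) ifelse(k <= length(concentrations), concentrations[k], 0)
  out <- lapply(seq_len(nrow(as_)), function(r) {
    i <- as_$i[r]; j <- as_$j[r]
    fwd <- as_$rate[r] * ck(i) * ck(j)
    m <- ds$i == i & ds$j == j
    rev <- if (any(m)) ds$rate[m][1] * ck(i + j) else 0
    rev_ev <- if (any(m)) ds$events[m][1] else 0
    data.frame(i = i, j = j, forward = fwd, reverse = rev,
               ratio = if (rev > 0) fwd / rev else Inf,
               reverse_events = rev_ev)
  })
  do.call(rbind, out)
}
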