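# helper: frame with explicit positions in a periodic box
pf <- function(pos, box, species = NULL) {
  particle_frame(as.matrix(pos), box = box, species = species)
}

test_that("contact criterion bonds pairs within the inflection radius", {
  pot <- mie_potential()
  crit <- bond_criterion("simulation", potential = pot)
  expect_equal(crit$cutoff, (31 / 14)^0.1, tolerance = 1e-9)
  f <- pf(rbind(c(1, 1, 1), c(1 + 1.05, 1, 1), c(5, 5, 5)), box = 10)
  g <- contact_pairs(f, crit)
  expect_equal(nrow(g), 1)  # 1.05 < 1.0827 bonded; far particle isolated
  f2 <- pf(rbind(c(1, 1, 1), c(1 + 1.2, 1, 1)), box = 10)
  expect_equal(nrow(contact_pairs(f2, crit)), 0)
  # per-pair scaling: a b-b pair at 1.15 sigma_aa is within 1.0827 * 1.1
  f3 <- pf(rbind(c(1, 1, 1), c(2.15, 1, 1)), box = 10, species = c(1L, 1L))
  expect_equal(nrow(contact_pairs(f3, crit)), 1)
  # experiment criterion: fixed distance, open boundaries
  ce <- bond_criterion("experiment", r = 1)
  expect_equal(ce$cutoff, 2.6)
  pts <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  expect_equal(nrow(contact_pairs(pts, ce)), 1)
  expect_equal(nrow(contact_pairs(rbind(c(0, 0, 0), c(2.7, 0, 0)), ce)), 0)
})

test_that("cluster labelling matches an independent union-find oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 120
    L <- 9
    f <- pf(matrix(runif(3 * n, 0, L), n, 3), box = L)
    g <- contact_pairs(f, bond_criterion(cutoff = 1.2), size_ratio = 1)
    cs <- cluster_labels(g)
    # oracle: plain union-find over the same edges
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (nrow(g) > 0)
      for (e in seq_len(nrow(g))) {
        ri <- find(g$i[e]); rj <- find(g$j[e])
        if (ri != rj) parent[ri] <- rj
      }
    roots <- vapply(seq_len(n), find, integer(1))
    expect_equal(length(unique(roots)), length(cs$sizes))
    # identical partitions up to relabelling
    expect_true(all(tapply(cs$labels, roots, function(x) length(unique(x))) == 1))
  }
  # degenerate cases
  f0 <- pf(matrix(c(0, 0, 0, 3, 3, 3), 2, 3, byrow = TRUE), box = 8)
  cs0 <- cluster_labels(contact_pairs(f0, bond_criterion(cutoff = 1.1),
                                      size_ratio = 1))
  expect_equal(cs0$sizes, c(1, 1))
  expect_equal(sum(cs0$sizes), 2)
})

test_that("mean coordination number counts bonded neighbours", {
  # linear trimer: degrees 1, 2, 1 -> z = 4/3
  f <- pf(rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)), box = 10)
  g <- contact_pairs(f, bond_criterion(cutoff = 1.1), size_ratio = 1)
  expect_equal(mean_coordination(g), 4 / 3)
  # regular tetrahedron, all bonded: complete graph on 4 -> z = 3
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3)) + 2
  gt <- contact_pairs(pf(tet, box = 10), bond_criterion(cutoff = 1.05),
                      size_ratio = 1)
  expect_equal(mean_coordination(gt), 3)
  # no bonds -> 0; adding bonds can only increase z
  g0 <- contact_pairs(f, bond_criterion(cutoff = 0.5), size_ratio = 1)
  expect_equal(mean_coordination(g0), 0)
  expect_gt(mean_coordination(g), mean_coordination(g0))
})

test_that("radius of gyration handles singletons, dimers and unwrapping", {
  expect_equal(gyration_radius(matrix(c(1, 2, 3), 1, 3)), 0)
  d <- 0.9
  expect_equal(gyration_radius(rbind(c(0, 0, 0), c(d, 0, 0))), d / 2)
  # collinear trimer, spacing d: rms distance from centre = sqrt(2/3) d
  tri <- rbind(c(-d, 0, 0), c(0, 0, 0), c(d, 0, 0))
  expect_equal(gyration_radius(tri), sqrt(2 / 3) * d)
  # periodic unwrapping: a chain straddling the boundary has the same R_g
  # as the same chain in open space
  L <- 10
  chain_open <- cbind(seq(0, 4, by = 1), 0, 0)
  chain_wrap <- chain_open
  chain_wrap[, 1] <- (chain_open[, 1] + L - 2) %% L  # crosses the x boundary
  f <- pf(sweep(chain_wrap, 2, c(0, 5, 5), "+"), box = L)
  g <- contact_pairs(f, bond_criterion(cutoff = 1.1), size_ratio = 1)
  expect_equal(gyration_radius(NULL, graph = g),
               gyration_radius(chain_open), tolerance = 1e-12)
})

test_that("correlation length implements the weighted cluster formula", {
  fake <- structure(list(sizes = c(2, 4), rg = c(1, 2), labels = c(1, 1, 2, 2, 2, 2),
                         spanning = c(FALSE, FALSE), n_particles = 6,
                         box = 100, periodic = TRUE,
                         unwrapped = matrix(0, 6, 3)),
                    class = "cluster_set")
  # xi^2 = 2 (1*4 + 4*16) / (4 + 16) = 6.8
  expect_equal(correlation_length(fake)^2, 6.8)
  # single cluster: xi = sqrt(2) R_g
  one <- fake; one$sizes <- 5; one$rg <- 1.7; one$spanning <- FALSE
  expect_equal(correlation_length(one), sqrt(2) * 1.7)
  # all singletons: 0
  sing <- fake; sing$sizes <- rep(1, 6); sing$rg <- rep(0, 6)
  expect_equal(correlation_length(sing), 0)
  # excluding the largest cluster drops its contribution
  expect_equal(correlation_length(fake, include_largest = FALSE)^2,
               2 * 1 * 4 / 4)
})

test_that("correlation length is invariant under rigid translation", {
  set.seed(13)
  af <- assemble_frame(n_clusters = 25, tau = 1.5, k_c = 10, d_f = 2,
                       seed = 31)
  crit <- bond_criterion(cutoff = 1.1)
  x1 <- correlation_length(cluster_labels(contact_pairs(af$frame, crit,
                                                        size_ratio = 1)))
  shifted <- af$frame
  shifted$positions <- (shifted$positions + 3.7) %% shifted$box
  x2 <- correlation_length(cluster_labels(contact_pairs(shifted, crit,
                                                        size_ratio = 1)))
  expect_equal(x1, x2, tolerance = 1e-9)
})

test_that("mass histogram counts, bins and drops the largest cluster", {
  fake <- structure(list(sizes = c(1, 1, 2), rg = c(0, 0, 0.5),
                         labels = c(1, 2, 3, 3), spanning = rep(FALSE, 3),
                         n_particles = 4, box = 10, periodic = TRUE,
                         unwrapped = matrix(0, 4, 3)),
                    class = "cluster_set")
  h <- mass_histogram(fake)
  expect_equal(h$k, c(1, 2))
  expect_equal(h$count, c(2, 1))
  h2 <- mass_histogram(fake, drop_largest = TRUE)
  expect_equal(sum(h2$count), 2)
  # log-binned counts aggregate the linear counts
  set.seed(3)
  sizes <- sample_cluster_sizes(500, tau = 1.5, k_c = 40)
  fs <- fake; fs$sizes <- sizes
  hl <- mass_histogram(fs, log_binned = TRUE, bins_per_decade = 3)
  expect_equal(sum(hl$count), length(sizes))
})

test_that("percolation is detected via self-image connectivity", {
  L <- 10
  # chain of 10 particles spaced 1.0 along x wraps onto itself
  chain <- cbind(0:9 + 0.5, 5, 5)
  f <- pf(chain, box = L)
  cs <- cluster_labels(contact_pairs(f, bond_criterion(cutoff = 1.05),
                                     size_ratio = 1))
  lc <- largest_clusters(cs)
  expect_true(lc$percolating)
  expect_equal(lc$f_z, 1)
  # two equal non-spanning clusters: f_z = second = 0.5, no percolation
  cl1 <- cbind(seq(0, 2), 2, 2)
  cl2 <- cbind(seq(0, 2), 7, 7)
  f2 <- pf(rbind(cl1, cl2) + 0.5, box = L)
  cs2 <- cluster_labels(contact_pairs(f2, bond_criterion(cutoff = 1.05),
                                      size_ratio = 1))
  lc2 <- largest_clusters(cs2)
  expect_false(lc2$percolating)
  expect_equal(lc2$f_z, 0.5)
  expect_equal(lc2$second_fraction, 0.5)
})

test_that("fractal dimension distinguishes chains, random and compact clusters", {
  set.seed(17)
  mk <- function(df) {
    sizes <- round(10^seq(0.8, 2.6, length.out = 8))
    do.call(rbind, lapply(rep(sizes, 3), function(s) {
      p <- build_cluster(s, df)
      data.frame(size = s,
                 rg = sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2))))
    }))
  }
  f1 <- fractal_dimension(mk(1), size_window = c(5, 1e4), n_boot = 30)
  expect_equal(f1$exponent, 1, tolerance = 0.05)
  f3 <- fractal_dimension(mk(3), size_window = c(5, 1e4), n_boot = 30)
  expect_equal(f3$exponent, 3, tolerance = 0.3)
  expect_error(fractal_dimension(data.frame(size = c(5, 6), rg = c(1, 1))),
               "too few")
})

test_that("experimental double-threshold grouping separates bonding from clustering", {
  # two points at 3.0 r: same cluster (d_c = 3.5 r) but not bonded (d_0 = 2.6 r)
  p <- rbind(c(0, 0, 0), c(3, 0, 0))
  cs <- experiment_grouping(p, r = 1)
  expect_equal(length(cs$sizes), 1)
  expect_equal(nrow(attr(cs, "bonds")), 0)
  # 2.0 r: bonded and clustered
  cs2 <- experiment_grouping(rbind(c(0, 0, 0), c(2, 0, 0)), r = 1)
  expect_equal(length(cs2$sizes), 1)
  expect_equal(nrow(attr(cs2, "bonds")), 1)
  # 4.0 r: separate clusters
  cs3 <- experiment_grouping(rbind(c(0, 0, 0), c(4, 0, 0)), r = 1)
  expect_equal(length(cs3$sizes), 2)
})

test_that("frame metrics are internally consistent", {
  set.seed(23)
  af <- assemble_frame(n_clusters = 40, tau = 1.5, k_c = 15, d_f = 2,
                       seed = 8)
  m <- frame_metrics(af$frame, bond_criterion(cutoff = 1.1), size_ratio = 1)
  expect_gte(m$f_z, m$second_fraction)
  expect_gte(m$xi, 0)
  expect_equal(m$n_clusters, length(af$sizes))
  cs <- cluster_labels(contact_pairs(af$frame, bond_criterion(cutoff = 1.1),
                                     size_ratio = 1))
  expect_equal(sum(cs$sizes), nrow(af$frame$positions))
})
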