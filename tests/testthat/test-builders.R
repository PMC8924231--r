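test_that("dilute builder packs chains without overlap, deterministically", {
  mod <- homo_model(0.66)
  st <- build_dilute(10, mod, 50, seed = 1)
  expect_equal(nrow(st$positions), 390)
  prs <- agedrop:::cpp_neighbor_pairs(st$positions, st$box, 0.9)
  # only bonded neighbours may sit below 0.9 sigma... and bonds are at 1.0
  expect_equal(nrow(prs), 0)
  # packing fraction well below dilute limit
  expect_lt(390 * pi / 6 / prod(st$box), 0.01)
  st2 <- build_dilute(10, mod, 50, seed = 1)
  expect_identical(st$positions, st2$positions)
  expect_error(build_dilute(80, mod, 12, seed = 1, max_retries = 5L),
               "larger box")
})

test_that("droplet builder yields one compact near-spherical cluster", {
  mod <- homo_model(0.66)
  st <- build_droplet(20, mod, seed = 2)
  cl <- agedrop:::.largest_cluster(st$positions, st$box, 1.5)
  expect_gte(length(cl$members), 0.98 * nrow(st$positions))
  p <- agedrop:::.recenter_cluster(st$positions[cl$members, , drop = FALSE],
                                   st$box)
  expect_lt(shape_metrics(p)$relative_shape_anisotropy, 0.05)
  # centred in the box
  com <- colMeans(unwrap_positions(st))
  expect_lt(sqrt(sum((com - st$box / 2)^2)), 1.0)
  # single chain is trivially a droplet
  st1 <- build_droplet(1, mod, seed = 3)
  expect_equal(nrow(st1$positions), 39)
})

test_that("tangent pairs start as exactly two touching clusters", {
  mod <- hetero_model(5)
  st <- build_tangent_pair(8, 8, mod, seed = 4)
  n <- nrow(st$positions)
  half <- seq_len(n / 2)
  dmin <- agedrop:::.min_cross_distance(st$positions[half, ],
                                        st$positions[-half, ])
  expect_gte(dmin, 0.85)
  expect_lte(dmin, 1.6)
  # the pair resolves into exactly two cohesive bodies: chains linked only
  # when they share many bead contacts (droplet-internal neighbours share
  # hundreds; chains kissing across the touching plane share a handful)
  prs <- agedrop:::cpp_neighbor_pairs(st$positions, st$box, 1.5)
  chain_of <- (seq_len(n) - 1) %/% 39 + 1
  inter <- chain_of[prs[, 1]] != chain_of[prs[, 2]]
  key <- paste(pmin(chain_of[prs[inter, 1]], chain_of[prs[inter, 2]]),
               pmax(chain_of[prs[inter, 1]], chain_of[prs[inter, 2]]))
  tab <- table(key)
  strong_edges <- do.call(rbind, strsplit(names(tab)[tab >= 20], " "))
  g <- igraph::graph_from_edgelist(apply(strong_edges, 2, as.integer),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, 16 - igraph::vcount(g)))
  comp_sizes <- sort(igraph::components(g)$csize, decreasing = TRUE)
  expect_gte(sum(comp_sizes[1:2]), 14)   # two bodies hold nearly all chains
  expect_gte(comp_sizes[2], 6)
  # and the touching plane joins them into one bead-graph cluster
  expect_equal(largest_cluster_fraction(st$positions, st$box, st$topology,
                                        1.5), 1.0)
  # asymmetric pair accepted
  st2 <- build_tangent_pair(5, 12, mod, seed = 5)
  expect_equal(nrow(st2$positions), 17 * 39)
})

test_that("coexistence density is self-consistent and increases with eps_D", {
  mod <- homo_model(0.66)
  cx <- estimate_coexistence_density(mod, seed = 6, n_chains = 20L,
                                     equil_time = 40)
  expect_gt(cx$beads_per_sigma3, 0.2)
  expect_lt(cx$beads_per_sigma3, 1.2)
  # self-consistency: the reported density lies within its own core profile
  prof <- cx$profile
  core <- prof$rho[prof$r <= 2]
  expect_gt(cx$beads_per_sigma3, 0.5 * min(core))
  expect_lt(cx$beads_per_sigma3, 1.5 * max(core))
  # a state point below the phase-separation threshold errors distinctly
  # (roomy box + time so the droplet actually disperses)
  expect_error(estimate_coexistence_density(homo_model(0.2), seed = 6,
                                            n_chains = 12L, equil_time = 150,
                                            box = 35),
               "phase-separate")
  # monotone non-decreasing over the liquid range
  cx2 <- estimate_coexistence_density(homo_model(0.9), seed = 6,
                                      n_chains = 20L, equil_time = 40)
  expect_gte(cx2$beads_per_sigma3, cx$beads_per_sigma3)
})

test_that("brownian walker fixture encodes its own diffusion coefficient", {
  tr <- make_synthetic_fixtures("brownian_walkers",
                                list(n = 200, D_true = 0.5, n_frames = 150),
                                seed = 7)
  d <- frame_positions(tr, 150) - frame_positions(tr, 1)
  D <- mean(rowSums(d^2)) / (6 * (tr$times[150] - tr$times[1]))
  expect_equal(D, 0.5, tolerance = 0.05)
  # deterministic under the same seed
  tr2 <- make_synthetic_fixtures("brownian_walkers",
                                 list(n = 200, D_true = 0.5, n_frames = 150),
                                 seed = 7)
  expect_identical(tr$frames, tr2$frames)
})

test_that("geometric fixtures have their designed shapes", {
  rod <- make_synthetic_fixtures("rigid_rod", list(n = 60), seed = 1)
  expect_equal(shape_metrics(frame_positions(rod, 1))$relative_shape_anisotropy,
               1.0, tolerance = 1e-12)
  cloud <- make_synthetic_fixtures("rigid_sphere_cloud",
                                   list(n = 8000, radius = 10), seed = 2)
  expect_lt(shape_metrics(frame_positions(cloud, 1))$relative_shape_anisotropy,
            0.01)
  toy <- make_synthetic_fixtures("contact_toy", list(ab_distance = 1.1))
  sc <- strong_contacts(frame_positions(toy, 1), toy$box, toy$topology, 1.5)
  expect_equal(sc$count, 1)
})
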