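test_that("windowed MSD recovers Brownian ground truth across decades", {
  for (D_true in c(0.05, 0.5, 5)) {
    tr <- make_synthetic_fixtures(
      "brownian_walkers",
      list(n = 4000, D_true = D_true, n_frames = 250,
           dt_frame = 16 / (6 * D_true) / 40),  # windows resolve 4-sigma rule
      seed = round(100 * D_true))
    ds <- msd_windowed(tr, displacement_factor = 4)
    expect_gte(nrow(ds), 2)
    expect_true(all(abs(ds$D - D_true) / D_true < 0.05))
    expect_true(all(ds$displacement >= 4))
    expect_true(all(diff(ds$window_center) > 0))
  }
})

test_that("windowed MSD refuses static input unless partial windows allowed", {
  pos <- matrix(runif(50 * 3) * 30, 50, 3)
  frames <- array(rep(pos, each = 60), c(60, 50, 3))
  topo <- list(n_chains = 50L, n_beads = 1L,
               sequence = make_sequence("homopolymer", 1L))
  tr <- new_trajectory(frames, seq_len(60) - 1, rep(100, 3), topo)
  expect_error(msd_windowed(tr), "displaced")
  ds <- msd_windowed(tr, allow_partial = TRUE)
  expect_false(any(ds$displacement_ok))
  expect_lt(ds$D[1], 1e-10)
})

test_that("regime classification applies the kinetic threshold and plateau", {
  mk <- function(D) {
    d <- data.frame(window_center = seq(100, by = 200, length.out = length(D)),
                    D = D, span = 200, displacement = 4,
                    displacement_ok = TRUE)
    class(d) <- c("diffusion_series", "data.frame")
    d
  }
  # constant liquid plateau above threshold
  liq <- classify_regime(mk(rep(0.002, 6)), threshold = 2e-4)
  expect_equal(liq$label, "liquid")
  expect_false(liq$low_confidence)
  # exponential decay crossing the threshold at t* = 1000
  tt <- seq(100, by = 200, length.out = 10)
  D <- 0.002 * exp(-tt / 1000 * log(10))
  ser <- mk(D)
  ser$window_center <- tt
  age <- classify_regime(ser, threshold = 2e-4)
  expect_equal(age$label, "ageing")
  expect_lt(abs(age$onset_time - 1000), 200)  # within one window spacing
  # decaying but not yet crossed: ageing, low confidence, no onset
  dec <- classify_regime(mk(c(0.01, 0.005, 0.003, 0.002, 0.0015)),
                         threshold = 2e-4)
  expect_equal(dec$label, "ageing")
  expect_true(is.na(dec$onset_time))
  expect_true(dec$low_confidence)
})

test_that("strong contacts count only heterotypic inter-chain sticker pairs", {
  toy <- make_synthetic_fixtures("contact_toy", list(ab_distance = 1.1))
  pos <- frame_positions(toy, 1)
  sc <- strong_contacts(pos, toy$box, toy$topology, contact_cutoff = 1.5)
  expect_equal(sc$count, 1)
  expect_length(sc$chain_clusters, 1)
  expect_setequal(sc$chain_clusters[[1]], 1:2)
  # tighter cutoff excludes the pair
  expect_equal(strong_contacts(pos, toy$box, toy$topology, 1.0)$count, 0)
  # homotypic A-A at contact distance never counts: bring chain 2's first A
  # (bead 3 of chain 2 is spacer; use its bead 5 = stickerA) next to chain
  # 1's stickerA and push the B bead away
  pos2 <- pos
  pos2[39 + 12, ] <- c(5, 120, 50)           # remove the A-B contact
  pos2[39 + 5, ] <- pos[5, ] + c(0, 1.1, 0)  # A-A pair at 1.1 sigma
  expect_equal(strong_contacts(pos2, toy$box, toy$topology, 1.5)$count, 0)
})

test_that("contact counting matches the all-pairs oracle on random frames", {
  seqn <- make_sequence("uniform")
  box <- rep(12, 3)
  set.seed(99)
  for (rep in 1:30) {
    n_chains <- sample(2:4, 1)
    pos <- matrix(runif(n_chains * 39 * 3) * 12, ncol = 3)
    topo <- list(n_chains = n_chains, n_beads = 39L, sequence = seqn)
    mine <- strong_contacts(pos, box, topo, 1.5)
    oracle <- brute_strong_contacts(pos, box, topo, 1.5)
    expect_equal(mine$count, oracle$count)
    if (!is.null(oracle$edges)) {
      g <- igraph::graph_from_edgelist(oracle$edges, directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n_chains - igraph::vcount(g)))
      osz <- sort(Filter(function(s) s > 1, igraph::components(g)$csize))
      expect_equal(sort(lengths(mine$chain_clusters)), osz)
    } else {
      expect_length(mine$chain_clusters, 0)
    }
  }
})

test_that("condensate density recovers a constructed uniform sphere", {
  rho0 <- 0.6
  n <- 4000
  cloud <- make_synthetic_fixtures(
    "rigid_sphere_cloud", list(n = n, radius = (3 * n / (4 * pi * rho0))^(1 / 3)),
    seed = 5)
  cd <- condensate_density(frame_positions(cloud, 1), cloud$box,
                           cluster_cutoff = 2.0)
  expect_equal(cd$density, rho0, tolerance = 0.03)
  expect_false(cd$small_cluster)
  # small clusters fall back to the gyration-equivalent volume, flagged
  tiny <- matrix(rnorm(30 * 3), 30, 3) + 20
  cd2 <- condensate_density(tiny, rep(40, 3), cluster_cutoff = 5)
  expect_true(cd2$small_cluster)
  expect_gt(cd2$density, 0)
})

test_that("shape metrics match the pairwise-distance oracle and invariances", {
  set.seed(12)
  # random planar disc
  ang <- runif(200) * 2 * pi; rad <- sqrt(runif(200)) * 5
  disc <- cbind(rad * cos(ang), rad * sin(ang), 0)
  sm <- shape_metrics(disc)
  expect_equal(sm$gyration_eigenvalues, brute_gyration_eigs(disc),
               tolerance = 1e-10)
  # rigid rotation + translation invariance, kappa^2 in [0, 1]
  for (rep in 1:10) {
    pts <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 1, 0.2))
    s0 <- shape_metrics(pts)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    s1 <- shape_metrics(pts %*% R + matrix(rnorm(3), 20, 3, byrow = TRUE))
    expect_equal(s1$relative_shape_anisotropy, s0$relative_shape_anisotropy,
                 tolerance = 1e-9)
    expect_gte(s0$relative_shape_anisotropy, 0)
    expect_lte(s0$relative_shape_anisotropy, 1)
  }
  expect_true(shape_metrics(matrix(rnorm(9), 3, 3))$reduced_rank)
})

test_that("coalescence detector fires at the constructed merge time", {
  tr <- make_synthetic_fixtures("two_spheres_merging",
                                list(n_per_sphere = 1500, radius = 5,
                                     n_frames = 120, merge_frame = 80),
                                seed = 3)
  res <- coalescence_time(tr, sphericity_tol = 0.02, censor_time = 119)
  expect_equal(res$status, "fused")
  expect_false(res$censored)
  # fires at the constructed merge (frame 80 = time 79), within the dwell
  expect_lt(abs(res$tau_c - 79), 12)
  # stride invariance: subsampling finer than the dwell changes nothing
  sub <- new_trajectory(tr$frames[seq(1, 120, by = 2), , ],
                        tr$times[seq(1, 120, by = 2)], tr$box, tr$topology)
  res2 <- coalescence_time(sub, sphericity_tol = 0.02, censor_time = 119)
  expect_equal(res2$status, "fused")
  expect_lt(abs(res2$tau_c - res$tau_c), 3)  # stride finer than the dwell
  # static separated spheres censor at the censor time
  static <- new_trajectory(tr$frames[rep(1, 40), , ], tr$times[1:40],
                           tr$box, tr$topology)
  res3 <- coalescence_time(static, censor_time = 39)
  expect_equal(res3$status, "censored")
  expect_true(res3$censored)
})

test_that("border curve keeps crossings only and orders them by eps_S", {
  mk <- function(tt, D) {
    d <- data.frame(window_center = tt, D = D, span = diff(tt)[1],
                    displacement = 4, displacement_ok = TRUE)
    class(d) <- c("diffusion_series", "data.frame")
    d
  }
  tt <- seq(50, 2000, by = 50)
  lst <- list(
    "5.25" = mk(tt, 0.002 * exp(-tt / 1000 * log(10))),  # crosses at 1000
    "6.6"  = mk(tt, 0.002 * exp(-tt / 100 * log(10))),   # crosses at 100
    "5.0"  = mk(tt, rep(0.002, length(tt))))             # liquid
  bc <- border_curve(lst, threshold = 2e-4)
  expect_equal(bc$label, c("liquid", "ageing", "ageing"))
  ons <- bc$onset_time[bc$label == "ageing"]
  expect_lt(abs(ons[1] - 1000), 50)
  expect_lt(abs(ons[2] - 100), 50)
  expect_true(all(diff(ons) < 0))  # stronger binding arrests earlier
  # single-point input stays a single point
  expect_equal(nrow(border_curve(lst["6.6"], 2e-4)), 1)
})

test_that("real-units diffusion times reproduce the Einstein estimate", {
  expect_equal(diffusion_time_real_units(1.0, 5.0), 25 / 6)
  expect_equal(diffusion_time_real_units(1.0, 0.0), 0)
  t1 <- diffusion_time_real_units(1.0, 5.0)
  # 2-3 orders of deceleration: minutes to about an hour
  expect_equal(deceleration_time(t1, 2), 1250 / 3)
  expect_equal(deceleration_time(t1, 3), 12500 / 3)
})
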