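test_that("cell-list forces equal the all-pairs reference", {
  # dilute heteropolymer box (exercises exclusions and mixed well depths)
  mod <- hetero_model(5)
  st <- build_dilute(4, mod, 14, seed = 3)
  a <- compute_forces(st, mod)
  b <- agedrop:::compute_forces_ref(st, mod)
  expect_lt(max(abs(a$forces - b$forces)), 1e-10)
  expect_equal(a$energy, b$energy, tolerance = 1e-12)

  # denser small box (exercises minimum image through the cell grid)
  mod2 <- homo_model(0.66)
  st2 <- build_bulk(5, mod2, 0.35, seed = 7, relax_steps = 500L,
                    equil_time = 2)
  a2 <- compute_forces(st2, mod2)
  b2 <- agedrop:::compute_forces_ref(st2, mod2)
  expect_lt(max(abs(a2$forces - b2$forces)) /
              max(1, max(abs(b2$forces))), 1e-10)

  # Wang-Frenkel variant
  mod3 <- cg_model(make_sequence("uniform"), build_interaction_table(0.6),
                   potential_spec("wang_frenkel"))
  a3 <- compute_forces(st, mod3)
  b3 <- agedrop:::compute_forces_ref(st, mod3)
  expect_lt(max(abs(a3$forces - b3$forces)), 1e-10)
})

test_that("isolated systems have zero net force", {
  # single bead
  seq1 <- make_sequence("homopolymer", 1L)
  st <- simulation_state(matrix(5, 1, 3), rep(10, 3), seq1, 1L)
  f <- compute_forces(st, homo_model(0.5))
  expect_equal(max(abs(f$forces)), 0)
  # one chain, bonds dominate: translational invariance
  mod <- ideal_model()
  std <- build_dilute(1, mod, 30, seed = 2)
  f2 <- compute_forces(std, homo_model(0.66))
  expect_lt(max(abs(colSums(f2$forces))), 1e-9)
})

test_that("free-particle Langevin diffusion recovers kT/(m gamma)", {
  st <- free_bead_state(250, 60, seed = 4)
  mod <- ideal_model(1L)
  p <- engine_params(dt = 0.01, gamma = 1, seed = 9)
  st2 <- advance(st, mod, p, 15000, record_stride = 100)
  tr <- attr(st2, "trajectory")
  ds <- msd_windowed(tr, displacement_factor = 4)
  expect_equal(mean(ds$D), 1.0, tolerance = 0.05)
})

test_that("NVE dynamics conserves energy (gamma = 0 dimer oracle)", {
  # two nonbonded beads near the LJ minimum, small perturbation
  seq1 <- make_sequence("homopolymer", 1L)
  pos <- rbind(c(5, 5, 5), c(5 + 2^(1 / 6) + 0.01, 5, 5))
  st <- simulation_state(pos, rep(12, 3), seq1, 2L,
                         velocities = matrix(0, 2, 3))
  mod <- homo_model(1.0)
  p <- engine_params(dt = 0.005, gamma = 0, seed = 1)
  st2 <- advance(st, mod, p, 1e5, record_stride = 500)
  tr <- attr(st2, "trajectory")
  E <- tr$pe + tr$ke
  expect_lt(max(E) - min(E), 1e-4)
})

test_that("runs are bit-reproducible and continuable across checkpoints", {
  mod <- hetero_model(5)
  st <- build_dilute(3, mod, 13, seed = 5)
  p <- engine_params(dt = 0.01, gamma = 1, seed = 11)
  a <- advance(st, mod, p, 400)
  b <- advance(st, mod, p, 400)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)

  # split run == unsplit run (counter-based noise keyed on global step)
  half <- advance(st, mod, p, 200)
  full <- advance(half, mod, p, 200)
  expect_equal(full$positions, a$positions, tolerance = 1e-12)

  # checkpoint round trip preserves everything including image counts
  cp <- tempfile(fileext = ".chk")
  write_checkpoint(half, cp)
  resumed <- advance(read_checkpoint(cp), mod, p, 200)
  expect_identical(resumed$positions, full$positions)
  expect_identical(resumed$images, full$images)
  writeLines("garbage", cp)
  expect_error(read_checkpoint(cp), "checkpoint")
})

test_that("switching interactions rescales only the strong contacts", {
  mod <- hetero_model(6.6)
  st <- build_bulk(4, mod, 0.3, seed = 6, relax_steps = 500L, equil_time = 2)
  # frozen coordinates: E(eps_S) must be affine in eps_S with fixed weak part
  energies <- vapply(c(5.0, 5.8, 6.6), function(es) {
    m <- mod
    m$interactions <- build_interaction_table(mod$interactions$eps_D, es)
    compute_forces(st, m)$energy
  }, numeric(1))
  slope <- (energies[3] - energies[1]) / (6.6 - 5.0)
  expect_equal(energies[2], energies[1] + slope * 0.8, tolerance = 1e-9)

  # no-op switch leaves the model unchanged but logs the event
  sw <- switch_interactions(st, mod, mod$interactions)
  expect_equal(sw$model$interactions$matrix, mod$interactions$matrix)
  expect_length(sw$state$schedule, 1)
  expect_equal(sw$state$schedule[[1]]$eps_S, 6.6)
  # incompatible table rejected
  expect_error(switch_interactions(st, mod, "not a table"))
})

test_that("ideal 39-bead chains obey freely-jointed-chain statistics", {
  # chain relaxation (Rouse) time is ~50 tau*, so sampling must span many
  # multiples of it for the ensemble average to converge
  mod <- ideal_model()
  st <- build_dilute(80, mod, 100, seed = 8)
  p <- engine_params(dt = 0.01, gamma = 1, seed = 3)
  st <- advance(st, mod, p, 3000)  # decorrelate from the build
  st2 <- advance(st, mod, p, 50000, record_stride = 2500)
  tr <- attr(st2, "trajectory")
  nb <- tr$topology$n_beads
  e2e <- c(); b2 <- c()
  for (f in seq_len(n_frames(tr))) {
    pos <- frame_positions(tr, f)
    for (ch in seq_len(tr$topology$n_chains)) {
      rows <- ((ch - 1) * nb + 1):(ch * nb)
      e2e <- c(e2e, sum((pos[rows[nb], ] - pos[rows[1], ])^2))
      b2 <- c(b2, rowSums(diff(pos[rows, ])^2))
    }
  }
  expect_equal(mean(e2e) / ((nb - 1) * mean(b2)), 1.0, tolerance = 0.1)
})

test_that("observables are seed-invariant in distribution", {
  mod <- ideal_model(1L)
  p1 <- engine_params(dt = 0.01, gamma = 1, seed = 21)
  p2 <- engine_params(dt = 0.01, gamma = 1, seed = 22)
  st <- free_bead_state(120, 60, seed = 4)
  get_disp <- function(p) {
    st2 <- advance(st, mod, p, 4000, record_stride = 4000)
    tr <- attr(st2, "trajectory")
    rowSums((frame_positions(tr, 1) - unwrap_positions(st))^2)
  }
  d1 <- get_disp(p1); d2 <- get_disp(p2)
  expect_false(identical(d1, d2))
  ks <- suppressWarnings(stats::ks.test(d1, d2))
  expect_gt(ks$p.value, 0.01)
})
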