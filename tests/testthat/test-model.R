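test_that("sequence composition invariants hold for every patterning", {
  u <- make_sequence("uniform")
  expect_equal(u$n_beads, 39L)
  expect_equal(unname(table(u$roles)[c("stickerA", "stickerB", "spacer")]),
               c(3L, 2L, 34L), ignore_attr = TRUE)

  h <- make_sequence("half_chain")
  expect_equal(sum(h$roles == "stickerA"), 3L)
  expect_equal(sum(h$roles == "stickerB"), 2L)
  expect_true(all(which(h$roles != "spacer") < 20))

  hp <- make_sequence("homopolymer")
  expect_true(all(hp$roles == "spacer"))
  expect_length(hp$roles, 39L)
})

test_that("sequence validation rejects bad sticker placements", {
  expect_error(make_sequence("uniform", sticker_A = c(5, 12), sticker_B = c(12, 26)),
               "overlap")
  expect_error(make_sequence("uniform", sticker_A = c(5, 19, 44), sticker_B = c(12, 26)),
               "range")
  expect_error(make_sequence("half_chain", sticker_A = c(3, 11, 30), sticker_B = c(7, 15)),
               "first half")
})

test_that("interaction table obeys symmetry and the A-B-only strong rule", {
  tab <- build_interaction_table(0.5, 5.0)
  roles <- bead_roles()
  for (a in roles) for (b in roles) {
    expect_equal(well_depth(tab, a, b), well_depth(tab, b, a))
    strong <- setequal(c(a, b), c("stickerA", "stickerB"))
    expect_equal(well_depth(tab, a, b), if (strong) 5.0 else 0.5)
  }
  # degenerate equal-depth case: the homopolymer limit
  eq <- build_interaction_table(0.66, 0.66)
  expect_true(all(eq$matrix == 0.66))
  # default coupling rule
  cp <- build_interaction_table(0.525)
  expect_equal(cp$eps_S, 5.25)
  expect_equal(well_depth(cp, "stickerB", "stickerA"), 5.25)
  expect_error(build_interaction_table(-0.1), "positive")
  expect_error(build_interaction_table(0.5, 0.2), ">=")
})

test_that("Lennard-Jones energy has its textbook landmarks", {
  lj <- potential_spec("lennard_jones", shift = FALSE)
  expect_equal(pair_energy(lj, 2^(1 / 6), eps = 1), -1.0, tolerance = 1e-12)
  expect_equal(pair_energy(lj, 1, eps = 0.5), 0.0, tolerance = 1e-12)
  ljs <- potential_spec("lennard_jones", shift = TRUE)
  expect_equal(pair_energy(ljs, ljs$cutoff, eps = 3), 0.0)
  # continuity at the cutoff with the shift enabled
  expect_lt(abs(pair_energy(ljs, ljs$cutoff - 1e-9, eps = 1)), 1e-7)
  expect_error(pair_energy(lj, 0, eps = 1), "positive")
})

test_that("Wang-Frenkel well depth is exactly -eps at its minimum", {
  wf <- potential_spec("wang_frenkel")
  opt <- optimize(function(r) pair_energy(wf, r, eps = 1),
                  interval = c(0.9, wf$cutoff), tol = 1e-10)
  expect_equal(opt$objective, -1.0, tolerance = 1e-8)
  # closed-form minimum location for mu = nu = 1
  rmin <- wf$cutoff * sqrt(3 / (1 + 2 * (wf$cutoff)^2))
  expect_equal(opt$minimum, rmin, tolerance = 1e-6)
  # exactly finite-ranged: zero at the cutoff with zero slope
  expect_equal(pair_energy(wf, wf$cutoff, eps = 1), 0)
  expect_lt(abs(pair_energy(wf, wf$cutoff - 1e-6, eps = 1)), 1e-9)
  # markedly shorter-ranged than the LJ default
  expect_lt(wf$cutoff, potential_spec("lennard_jones")$cutoff)
})

test_that("pair_force is the negative gradient of pair_energy", {
  set.seed(42)
  h <- 1e-6
  for (form in c("lennard_jones", "wang_frenkel")) {
    spec <- potential_spec(form)
    for (rep in 1:20) {
      r <- runif(1, 0.85, spec$cutoff - 0.01)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      f <- pair_force(spec, r * u, eps = 0.7)
      # radial central difference
      dEdr <- (pair_energy(spec, r + h, 0.7) - pair_energy(spec, r - h, 0.7)) / (2 * h)
      expect_equal(sum(f * u), -dEdr, tolerance = 1e-5)
      # Newton's third law
      expect_equal(pair_force(spec, -r * u, 0.7), -f)
    }
    # zero force at the minimum (LJ: analytic location)
    if (form == "lennard_jones")
      expect_equal(max(abs(pair_force(spec, c(2^(1 / 6), 0, 0), 1))), 0,
                   tolerance = 1e-12)
  }
  expect_error(pair_force(potential_spec(), c(0, 0, 0), 1), "diverg")
})

test_that("bond energy is harmonic with matching gradient", {
  b <- bond_spec(k_bond = 100, r0 = 1)
  expect_equal(bond_energy(b, 1), 0)
  expect_equal(bond_energy(b, 2), 50)
  h <- 1e-6
  for (r in c(0.7, 1.0, 1.4)) {
    num <- (bond_energy(b, r + h) - bond_energy(b, r - h)) / (2 * h)
    expect_equal(num, b$k_bond * (r - b$r0), tolerance = 1e-5)
  }
})
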