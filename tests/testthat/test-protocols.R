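test_that("maturation protocol logs its switch and honours zero duration", {
  rec <- run_maturation_in_droplet(n_chains = 4, eps_S = 5, duration = 0,
                                   seed = 3)
  expect_s3_class(rec, "experiment_record")
  expect_length(rec$schedule, 1)
  expect_equal(rec$schedule[[1]]$eps_S, 5)
  expect_equal(nrow(rec$series$contacts), 1)
  expect_equal(nrow(rec$series$shape), 1)
  expect_false(rec$labels$evaporated)
})

test_that("coalescence matrix handles an empty grid and records cells", {
  empty <- run_coalescence_matrix(sizes = integer(0), eps_S_grid = numeric(0),
                                  censor_time = 10)
  expect_equal(nrow(empty$table), 0)
})

test_that("records re-run bit-identically from their config and seed", {
  mod <- homo_model(0.8)
  r1 <- run_nucleation_growth(mod, n_chains = 8, duration = 25,
                              density = 0.08, seed = 17)
  r2 <- run_nucleation_growth(mod, n_chains = 8, duration = 25,
                              density = 0.08, seed = 17)
  expect_identical(r1$series$shape, r2$series$shape)
  expect_identical(r1$labels$terminal_kappa2, r2$labels$terminal_kappa2)
  r3 <- run_nucleation_growth(mod, n_chains = 8, duration = 25,
                              density = 0.08, seed = 18)
  expect_false(identical(r1$series$shape, r3$series$shape))
})

test_that("llps scan flags a grid that sits entirely above the threshold", {
  sc <- scan_llps_threshold("homopolymer", c(0.66, 0.8), n_chains = 18,
                            duration = 350, density = 0.08, seed = 5)
  expect_equal(sc$boundary_flag, "threshold_at_or_below_grid")
  expect_equal(sc$threshold, 0.66)
  expect_true(all(sc$table$llps))
})

test_that("hysteresis driver validates schedules and logs every leg", {
  expect_error(run_hysteresis(c(5, 5), n_chains = 6, leg_duration = 0.01,
                              seed = 1),
               "shorter than")
  rec <- run_hysteresis(c(5, 5), n_chains = 6, leg_duration = 15,
                        density = 0.08, seed = 1)
  expect_length(rec$schedule, 2)
  expect_length(rec$series$legs, 2)
  expect_equal(rec$series$legs[[1]]$eps_S, 5)
  expect_false(is.null(rec$series$legs[[2]]$shape))
})
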