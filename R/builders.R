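# Builders: initial conditions for every experiment, plus analytic fixture
# generators for testing the analysis code without running the engine.

# grow one chain as a (weakly) self-avoiding random walk from `start`;
# consecutive beads at the bond length, non-bonded beads kept >= min_dist
.grow_chain <- function(n_beads, r0, start, min_dist = 0.9,
                        inside = NULL, max_tries = 80L) {
  pos <- matrix(NA_real_, n_beads, 3)
  pos[1, ] <- start
  for (k in seq_len(n_beads - 1L)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      u <- rnorm(3)
      cand <- pos[k, ] + r0 * u / sqrt(sum(u^2))
      if (!is.null(inside) && !inside(cand)) next
      if (k >= 2) {
        d2 <- rowSums(sweep(pos[seq_len(k - 1L), , drop = FALSE], 2, cand)^2)
        if (min(d2) < min_dist^2) next
      }
      pos[k + 1L, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  pos
}

#' Build a dilute homogeneous box
#'
#' Chains are placed as self-avoiding random walks with no inter-bead pair
#' closer than `min_dist`. Used as the starting point for nucleation-and-
#' growth and phase-separation scans.
#'
#' @param n_chains Number of chains.
#' @param model A `cg_model`.
#' @param box Length-3 box vector, or a single edge length (sigma).
#' @param seed Integer seed (placement is seed-deterministic).
#' @param min_dist Minimum allowed inter-bead distance (sigma).
#' @param max_retries Chain placement retries before giving up.
#' @return A `simulation_state`.
#' @export
build_dilute <- function(n_chains, model, box, seed = 1L, min_dist = 0.9,
                         max_retries = 200L) {
  if (length(box) == 1) box <- rep(box, 3)
  seqn <- model$sequence
  nb <- seqn$n_beads
  old <- .set_local_seed(seed)
  on.exit(.restore_seed(old))
  placed <- NULL
  for (c_i in seq_len(n_chains)) {
    ok <- FALSE
    for (tr in seq_len(max_retries)) {
      start <- runif(3) * box
      ch <- .grow_chain(nb, model$bonds$r0, start, min_dist)
      if (is.null(ch)) next
      if (!is.null(placed)) {
        all_pos <- .wrap_positions(rbind(placed, ch), box)
        prs <- cpp_neighbor_pairs(all_pos, box, min_dist)
        np <- nrow(placed)
        cross <- prs[, 1] <= np & prs[, 2] > np |
                 prs[, 2] <= np & prs[, 1] > np
        if (any(cross)) next
      }
      placed <- rbind(placed, ch)
      ok <- TRUE
      break
    }
    if (!ok) stop("failed to place chain ", c_i, " after ", max_retries,
                  " retries; try a larger box")
  }
  simulation_state(placed, box, seqn, n_chains)
}

#' Build a dense bulk box at a target density
#'
#' Places chains as random walks at the target bead density (overlaps
#' allowed), then removes overlaps with a short force-capped relaxation
#' followed by a brief equilibration. Used for condensed-phase NVT runs at
#' the coexistence density.
#'
#' @param n_chains Number of chains.
#' @param model A `cg_model`.
#' @param density Target bead density (beads / sigma^3).
#' @param seed Integer seed.
#' @param relax_steps Steps of capped-force relaxation at a reduced timestep.
#' @param equil_time Equilibration span (tau*) at production settings.
#' @return A `simulation_state`.
#' @export
build_bulk <- function(n_chains, model, density, seed = 1L,
                       relax_steps = 3000L, equil_time = 50) {
  nb <- model$sequence$n_beads
  edge <- (n_chains * nb / density)^(1 / 3)
  if (edge < 2 * model$potential$cutoff)
    stop("target density too high for the cutoff: box edge ", signif(edge, 4))
  box <- rep(edge, 3)
  old <- .set_local_seed(seed)
  on.exit(.restore_seed(old))
  pos <- NULL
  for (c_i in seq_len(n_chains)) {
    ch <- NULL
    while (is.null(ch))
      ch <- .grow_chain(nb, model$bonds$r0, runif(3) * box, min_dist = 0.8)
    pos <- rbind(pos, ch)
  }
  st <- simulation_state(pos, box, model$sequence, n_chains)
  # push overlapping beads apart gently, then thermalise
  p_relax <- engine_params(dt = 0.002, gamma = 5, seed = seed, force_cap = 100)
  st <- suppressWarnings(advance(st, model, p_relax, relax_steps))
  p_eq <- engine_params(dt = 0.005, gamma = 1, seed = seed + 1L)
  advance(st, model, p_eq, max(1L, round(equil_time / p_eq$dt)))
}

#' Build a preformed spherical droplet
#'
#' Chains are grown inside a sphere at a liquid-like packing density and the
#' cluster is relaxed under homogeneous weak-liquid interactions (uniform
#' well depth `prep_eps`) until it is compact and near-spherical. Ageing
#' protocols then switch on the target interaction table.
#'
#' @param n_chains Number of chains in the droplet.
#' @param model A `cg_model` (its sequence/bonds/potential are used; the
#'   droplet is pre-equilibrated with uniform `prep_eps` interactions).
#' @param seed Integer seed.
#' @param prep_eps Uniform well depth (kBT) for pre-equilibration; the
#'   default 0.66 is a comfortably liquid state point.
#' @param prep_density Initial packing density (beads / sigma^3).
#' @param relax_time Relaxation span (tau*).
#' @param box Optional box; default scales with the droplet diameter.
#' @param kappa_tol Maximum allowed relative shape anisotropy after
#'   relaxation.
#' @return A `simulation_state` with the droplet centred in the box.
#' @export
build_droplet <- function(n_chains, model, seed = 1L, prep_eps = 0.66,
                          prep_density = 0.45, relax_time = 60,
                          box = NULL, kappa_tol = 0.05) {
  nb <- model$sequence$n_beads
  R <- (3 * n_chains * nb / (4 * pi * prep_density))^(1 / 3)
  if (is.null(box)) box <- rep(max(4 * R, 2 * R + 8, 6.5), 3)
  if (length(box) == 1) box <- rep(box, 3)
  centre <- box / 2
  old <- .set_local_seed(seed)
  on.exit(.restore_seed(old))
  inside <- function(p) sum((p - centre)^2) <= R^2
  pos <- NULL
  for (c_i in seq_len(n_chains)) {
    ch <- NULL
    tries <- 0L
    while (is.null(ch)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      start <- centre + runif(1)^(1 / 3) * max(R - 1, 0.1) * u
      ch <- .grow_chain(nb, model$bonds$r0, start, min_dist = 0.8,
                        inside = inside)
      tries <- tries + 1L
      if (tries > 500L) stop("droplet packing failed; lower prep_density")
    }
    pos <- rbind(pos, ch)
  }
  prep_model <- model
  prep_model$interactions <- build_interaction_table(prep_eps, prep_eps)
  st <- simulation_state(pos, box, model$sequence, n_chains)
  p_relax <- engine_params(dt = 0.002, gamma = 5, seed = seed, force_cap = 100)
  st <- suppressWarnings(advance(st, prep_model, p_relax, 2500L))
  p_eq <- engine_params(dt = 0.005, gamma = 1, seed = seed + 1L)
  if (n_chains > 1) {
    for (round in 1:6) {
      st <- advance(st, prep_model, p_eq, round(relax_time / p_eq$dt))
      cl <- .largest_cluster(st$positions, st$box, 1.5)
      sm <- shape_metrics(.recenter_cluster(st$positions[cl$members, , drop = FALSE],
                                            st$box))
      if (length(cl$members) >= 0.98 * nrow(st$positions) &&
          sm$relative_shape_anisotropy < kappa_tol) break
    }
    frac <- length(cl$members) / nrow(st$positions)
    if (frac < 0.9)
      stop("droplet fragmented during relaxation: largest-cluster fraction ",
           signif(frac, 3))
  }
  # recentre the droplet at the box centre
  upos <- unwrap_positions(st)
  com <- colMeans(upos)
  st$positions <- .wrap_positions(sweep(upos, 2, com - centre), st$box)
  st$images <- matrix(0L, nrow(upos), 3)
  st
}

#' Build two tangent droplets
#'
#' Two droplets are prepared independently, given random mutual orientations,
#' and placed with their surfaces in near contact (closest inter-droplet bead
#' distance about 1 sigma) along the x axis of a box sized to three merged
#' diameters per axis.
#'
#' @param n1,n2 Chain counts of the two droplets.
#' @param model A `cg_model`.
#' @param seed Integer seed.
#' @param gap Target surface-to-surface distance (sigma).
#' @param ... Passed to [build_droplet()].
#' @return A `simulation_state` containing both droplets.
#' @export
build_tangent_pair <- function(n1, n2, model, seed = 1L, gap = 1.0, ...) {
  nb <- model$sequence$n_beads
  d1 <- build_droplet(n1, model, seed = seed, ...)
  d2 <- build_droplet(n2, model, seed = seed + 1000L, ...)
  Rm <- (3 * (n1 + n2) * nb / (4 * pi * 0.45))^(1 / 3)
  box <- rep(max(6 * Rm, 20), 3)
  centre <- box / 2
  p1 <- sweep(unwrap_positions(d1), 2, colMeans(unwrap_positions(d1)))
  p2 <- sweep(unwrap_positions(d2), 2, colMeans(unwrap_positions(d2)))
  old <- .set_local_seed(seed + 2000L)
  on.exit(.restore_seed(old))
  for (attempt in 1:40) {
    rot <- .random_rotation()
    q2 <- p2 %*% rot
    # bring droplet 2 in from +x until the closest approach equals the gap
    off <- max(p1[, 1]) - min(q2[, 1]) + gap + 2
    for (iter in 1:30) {
      shifted <- q2
      shifted[, 1] <- shifted[, 1] + off
      dmin <- .min_cross_distance(p1, shifted)
      if (abs(dmin - gap) < 0.05) break
      off <- off - (dmin - gap)
    }
    if (dmin >= 0.9 * gap - 1e-9 && dmin <= 1.5) {
      pos <- rbind(p1, shifted)
      pos <- sweep(pos, 2, colMeans(pos) - centre)
      st <- simulation_state(pos, box, model$sequence, n1 + n2)
      return(st)
    }
  }
  stop("failed to place tangent droplets without overlap")
}

.min_cross_distance <- function(a, b) {
  # chunked to bound memory
  best <- Inf
  idx <- split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / 500))
  for (ii in idx) {
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), `+`) -
      2 * a[ii, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

.random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-12) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Estimate the coexistence (condensate core) density
#'
#' Builds a droplet, runs it with the target model, and reads the plateau of
#' its own radial density profile. Used to size bulk NVT boxes at the
#' equilibrium condensate density. A model below the phase-separation
#' threshold loses its droplet and raises an error naming the state point.
#'
#' @param model A `cg_model`.
#' @param seed Integer seed.
#' @param n_chains Droplet size used for the estimate.
#' @param equil_time Run span (tau*) with the target model before measuring.
#' @param params Optional `engine_params`.
#' @param ... Passed to [build_droplet()] (e.g. a larger `box` so that a
#'   dispersing system is recognisable as such).
#' @return List with `beads_per_sigma3`, `chains_per_sigma3` and the radial
#'   `profile` data frame.
#' @export
estimate_coexistence_density <- function(model, seed = 1L, n_chains = 40L,
                                         equil_time = 150, params = NULL,
                                         ...) {
  st <- build_droplet(n_chains, model, seed = seed, ...)
  if (is.null(params)) params <- engine_params(dt = 0.005, gamma = 1, seed = seed)
  st <- advance(st, model, params, round(equil_time / params$dt))
  cl <- .largest_cluster(st$positions, st$box, 1.5)
  frac <- length(cl$members) / nrow(st$positions)
  dens <- condensate_density(st$positions, st$box, cluster_cutoff = 1.5)
  # a percolating gas can masquerade as one big cluster; a genuine
  # condensed phase must also be liquid-dense
  if (frac < 0.5 || dens$density < 0.2)
    stop(sprintf(paste0("no stable droplet at eps_D = %.3g, eps_S = %.3g ",
                        "(largest-cluster fraction %.2f, core density %.3g):",
                        " state point does not phase-separate"),
                 model$interactions$eps_D, model$interactions$eps_S, frac,
                 dens$density))
  list(beads_per_sigma3 = dens$density,
       chains_per_sigma3 = dens$density / model$sequence$n_beads,
       profile = dens$profile)
}

#' Synthetic analysis fixtures
#'
#' Generates trajectories with analytically known ground truth, used to test
#' the analysis code independently of the engine:
#' \describe{
#'   \item{brownian_walkers}{independent Brownian particles with diffusion
#'     coefficient `D_true` (params: `n`, `D_true`, `n_frames`, `dt_frame`).}
#'   \item{rigid_sphere_cloud}{static uniform-density ball (params: `n`,
#'     `radius` or `density`, `n_frames`).}
#'   \item{rigid_rod}{static collinear points (params: `n`, `length`).}
#'   \item{two_spheres_merging}{two separated balls that become one ball at
#'     frame `merge_frame` (params: `n_per_sphere`, `radius`, `n_frames`,
#'     `merge_frame`).}
#'   \item{contact_toy}{two 39-bead chains with one complementary A-B pair
#'     placed at distance `ab_distance` (param), all other beads far apart.}
#' }
#'
#' @param kind Fixture name (see Details).
#' @param params Named list of parameters.
#' @param seed Integer seed.
#' @return A `cg_trajectory`.
#' @export
make_synthetic_fixtures <- function(kind, params = list(), seed = 1L) {
  old <- .set_local_seed(seed)
  on.exit(.restore_seed(old))
  p <- params
  switch(kind,
    brownian_walkers = {
      n <- p$n %||% 100L; D <- p$D_true %||% 0.5
      nf <- p$n_frames %||% 200L; dtf <- p$dt_frame %||% 1.0
      big <- 1e6
      frames <- array(0, c(nf, n, 3))
      x <- matrix(runif(n * 3) * big, n, 3)
      for (f in seq_len(nf)) {
        if (f > 1) x <- x + matrix(rnorm(n * 3, sd = sqrt(2 * D * dtf)), n, 3)
        frames[f, , ] <- x
      }
      topo <- list(n_chains = n, n_beads = 1L,
                   sequence = make_sequence("homopolymer", 1L))
      new_trajectory(frames, (seq_len(nf) - 1) * dtf, rep(big, 3), topo)
    },
    rigid_sphere_cloud = {
      n <- p$n %||% 5000L; nf <- p$n_frames %||% 3L
      R <- p$radius %||% if (!is.null(p$density)) (3 * n / (4 * pi * p$density))^(1 / 3) else 10
      u <- matrix(rnorm(n * 3), n, 3)
      u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3) * R
      box <- rep(8 * R, 3)
      pos <- sweep(u, 2, box / 2, `+`)
      frames <- array(rep(pos, each = nf), c(nf, n, 3))
      topo <- list(n_chains = n, n_beads = 1L,
                   sequence = make_sequence("homopolymer", 1L))
      new_trajectory(frames, seq_len(nf) - 1, box, topo)
    },
    rigid_rod = {
      n <- p$n %||% 50L; L <- p$length %||% 40
      pos <- cbind(seq(0, L, length.out = n) + 100, rep(100, n), rep(100, n))
      frames <- array(rep(pos, each = 1), c(1, n, 3))
      topo <- list(n_chains = n, n_beads = 1L,
                   sequence = make_sequence("homopolymer", 1L))
      new_trajectory(frames, 0, rep(1000, 3), topo)
    },
    two_spheres_merging = {
      ns <- p$n_per_sphere %||% 300L; R <- p$radius %||% 5
      nf <- p$n_frames %||% 120L; mf <- p$merge_frame %||% 80L
      box <- rep(20 * R, 3)
      ball <- function(n, centre) {
        u <- matrix(rnorm(n * 3), n, 3)
        sweep(u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3) * R, 2, centre, `+`)
      }
      frames <- array(0, c(nf, 2 * ns, 3))
      gap0 <- 6 * R
      for (f in seq_len(nf)) {
        if (f < mf) {
          # separation shrinks but the spheres stay disjoint until merge_frame
          sep <- 2 * R + 3 + (gap0 - 2 * R - 3) * (1 - (f - 1) / (mf - 1))
          frames[f, , ] <- rbind(ball(ns, box / 2 - c(sep / 2, 0, 0)),
                                 ball(ns, box / 2 + c(sep / 2, 0, 0)))
        } else {
          Rm <- R * 2^(1 / 3)
          u <- matrix(rnorm(2 * ns * 3), 2 * ns, 3)
          frames[f, , ] <- sweep(u / sqrt(rowSums(u^2)) *
                                   runif(2 * ns)^(1 / 3) * Rm, 2, box / 2, `+`)
        }
      }
      topo <- list(n_chains = 2L * ns, n_beads = 1L,
                   sequence = make_sequence("homopolymer", 1L))
      new_trajectory(frames, seq_len(nf) - 1, box, topo)
    },
    contact_toy = {
      d_ab <- p$ab_distance %||% 1.1
      seqn <- make_sequence("uniform")
      nb <- seqn$n_beads
      box <- rep(200, 3)
      # chain 1 along x, chain 2 parallel, far away except sticker A (bead 5
      # of chain 1) vs sticker B (bead 12 of chain 2) brought to d_ab
      c1 <- cbind(seq_len(nb) * 1.0, 50, 50)
      c2 <- cbind(seq_len(nb) * 1.0 + (5 - 12), 50 + d_ab, 50 + 30)
      c2[12, 3] <- 50  # drop that one B bead next to chain 1's first A bead
      pos <- rbind(c1, c2)
      frames <- array(pos, c(1, 2 * nb, 3))
      topo <- list(n_chains = 2L, n_beads = nb, sequence = seqn)
      new_trajectory(frames, 0, box, topo)
    },
    stop("unknown fixture kind: ", kind)
  )
}

# seed helpers: builders/fixtures are seed-deterministic without clobbering
# the caller's RNG stream
.set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
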