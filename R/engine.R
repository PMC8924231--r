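# Engine module: Langevin dynamics of many chains in a periodic box.
# The integrator is the BAOAB splitting (half kick / half drift / OU noise /
# half drift / half kick); with friction 0 it reduces to velocity Verlet and
# conserves energy, which the tests exploit as a validation oracle.

#' Engine parameters
#'
#' @param dt Timestep in tau*. Default 0.01; strong couplings
#'   (eps_S >= 5 kBT) are typically run at 0.005.
#' @param gamma Langevin friction in 1/tau*. 0 gives NVE dynamics (used for
#'   energy-conservation validation). Default 1.0, the conventional
#'   implicit-solvent friction for bead-spring polymer models.
#' @param kT Thermostat temperature in energy units; fixed at 1 by convention
#'   (interaction strengths are expressed directly in kBT).
#' @param seed Integer seed for the counter-based noise stream.
#' @param neighbor_skin Verlet-list skin (sigma). The list is rebuilt
#'   whenever any bead has moved more than half the skin since the last
#'   build, so no pair within the cutoff is ever missed.
#' @param force_cap Per-bead force-norm cap (energy/sigma); used only during
#'   initial relaxation of packed configurations, `Inf` (disabled) in
#'   production.
#' @return An object of class `engine_params`.
#' @export
engine_params <- function(dt = 0.01, gamma = 1.0, kT = 1.0, seed = 1L,
                          neighbor_skin = 0.4, force_cap = Inf) {
  stopifnot(dt > 0, gamma >= 0, kT > 0)
  structure(list(dt = dt, gamma = gamma, kT = kT, seed = as.integer(seed),
                 neighbor_skin = neighbor_skin, force_cap = force_cap),
            class = "engine_params")
}

#' Construct a simulation state
#'
#' A state holds wrapped positions plus per-bead periodic image counts (so
#' unwrapped coordinates, needed for mean-square displacements, are exact),
#' velocities, the orthorhombic box, the current time and global step counter,
#' and the chain topology.
#'
#' @param positions n x 3 matrix of bead positions (sigma).
#' @param box Length-3 vector of box edges (sigma).
#' @param sequence The `protein_sequence` shared by all chains.
#' @param n_chains Number of chains; `nrow(positions)` must equal
#'   `n_chains * sequence$n_beads`.
#' @param velocities Optional n x 3 matrix; defaults to Maxwell-Boltzmann at
#'   `kT` drawn from R's RNG.
#' @param images Optional n x 3 integer matrix of image counts (default 0).
#' @param time Simulation time in tau*.
#' @param kT Temperature for default velocity draw.
#' @return An object of class `simulation_state`.
#' @export
simulation_state <- function(positions, box, sequence, n_chains,
                             velocities = NULL, images = NULL, time = 0,
                             kT = 1.0) {
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0),
            n == n_chains * sequence$n_beads)
  if (is.null(velocities))
    velocities <- matrix(rnorm(3 * n, sd = sqrt(kT)), n, 3)
  if (is.null(images)) images <- matrix(0L, n, 3)
  storage.mode(images) <- "integer"
  wrapped <- sweep(positions, 2, box, function(p, L) p - L * floor(p / L))
  images <- images + matrix(as.integer(floor(t(t(positions) / box))), n, 3)
  structure(list(positions = wrapped, images = images,
                 velocities = velocities, box = as.numeric(box),
                 time = time, step_count = 0,
                 topology = list(n_chains = as.integer(n_chains),
                                 n_beads = sequence$n_beads,
                                 sequence = sequence),
                 schedule = list()),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat("<simulation_state>", x$topology$n_chains, "chains x",
      x$topology$n_beads, "beads, box", paste(signif(x$box, 4), collapse = " x "),
      "sigma, t =", signif(x$time, 6), "tau*\n")
  invisible(x)
}

#' Unwrapped bead coordinates of a state
#' @param state A `simulation_state`.
#' @return n x 3 matrix of unwrapped positions.
#' @export
unwrap_positions <- function(state) {
  state$positions + sweep(state$images, 2, state$box, `*`)
}

.state_engine_args <- function(state, model) {
  list(type = .topology_types(state$topology$sequence, state$topology$n_chains),
       eps = .model_eps_matrix(model),
       form = .model_form_code(model),
       sigma = model$units$sigma,
       cutoff = model$potential$cutoff,
       shift = model$potential$shift,
       bonds = .topology_bonds(state$topology$n_beads, state$topology$n_chains),
       kbond = model$bonds$k_bond,
       r0 = model$bonds$r0)
}

#' Compute forces and potential energy
#'
#' Cell-list evaluation of nonbonded plus bonded forces on the current state.
#' Beads closer than 0.5 sigma trigger an overlap warning (and are the reason
#' the force cap exists for initial relaxation).
#'
#' @param state A `simulation_state`.
#' @param model A `cg_model`.
#' @param force_cap Optional per-bead force-norm cap; `Inf` disables.
#' @return List with `forces` (n x 3) and `energy` (kBT).
#' @export
compute_forces <- function(state, model, force_cap = Inf) {
  a <- .state_engine_args(state, model)
  res <- cpp_compute_forces(state$positions, state$box, a$type, a$eps, a$form,
                            a$sigma, a$cutoff, a$shift, a$bonds, a$kbond,
                            a$r0, if (is.finite(force_cap)) force_cap else -1)
  if (res$n_overlaps > 0 && !is.finite(force_cap))
    warning(sprintf("%d bead pair(s) closer than 0.5 sigma (uncapped forces)",
                    res$n_overlaps))
  res[c("forces", "energy")]
}

# Pure-R all-pairs reference used as the oracle for the cell-list engine.
# Deliberately naive: double loop over pairs via distance matrix, minimum
# image, no neighbor structure.
compute_forces_ref <- function(state, model) {
  n <- nrow(state$positions)
  pos <- state$positions
  box <- state$box
  types <- .ROLES[.topology_types(state$topology$sequence,
                                  state$topology$n_chains) + 1L]
  bonds <- .topology_bonds(state$topology$n_beads, state$topology$n_chains) + 1L
  bonded <- matrix(FALSE, n, n)
  bonded[bonds] <- TRUE
  bonded[bonds[, 2:1, drop = FALSE]] <- TRUE
  F <- matrix(0, n, 3)
  pe <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- pos[i, ] - pos[j, ]
      dv <- dv - box * round(dv / box)
      r <- sqrt(sum(dv^2))
      if (!bonded[i, j] && r < model$potential$cutoff) {
        eps <- well_depth(model$interactions, types[i], types[j])
        pe <- pe + pair_energy(model$potential, r, eps, model$units$sigma)
        f <- pair_force(model$potential, dv, eps, model$units$sigma)
        F[i, ] <- F[i, ] + f
        F[j, ] <- F[j, ] - f
      }
    }
  }
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    dv <- pos[i, ] - pos[j, ]
    dv <- dv - box * round(dv / box)
    r <- sqrt(sum(dv^2))
    pe <- pe + bond_energy(model$bonds, r)
    fr <- -model$bonds$k_bond * (r - model$bonds$r0) / r
    F[i, ] <- F[i, ] + fr * dv
    F[j, ] <- F[j, ] - fr * dv
  }
  list(forces = F, energy = pe)
}

#' Advance the dynamics
#'
#' Runs `n_steps` of Langevin (or, with `gamma = 0`, NVE) dynamics. The run is
#' bit-reproducible given the state, model, params and step count: noise is
#' generated by a counter-based stream keyed on (seed, global step, bead,
#' axis), so continuing a run in several calls gives the same trajectory as
#' one long call.
#'
#' @param state A `simulation_state`.
#' @param model A `cg_model`.
#' @param params An `engine_params`.
#' @param n_steps Number of timesteps.
#' @param record_stride If > 0, record an unwrapped-coordinate frame every
#'   this many steps; the recorded trajectory is attached as
#'   `attr(state, "trajectory")`.
#' @return The advanced `simulation_state`.
#' @export
advance <- function(state, model, params, n_steps, record_stride = 0L) {
  stopifnot(inherits(state, "simulation_state"), inherits(model, "cg_model"),
            inherits(params, "engine_params"), n_steps >= 0)
  if (model$potential$cutoff > min(state$box) / 2)
    stop("cutoff exceeds half the smallest box edge")
  if (n_steps == 0) return(state)
  a <- .state_engine_args(state, model)
  res <- cpp_run_langevin(state$positions, state$images, state$velocities,
                          state$box, a$type, a$eps, a$form, a$sigma, a$cutoff,
                          a$shift, a$bonds, a$kbond, a$r0,
                          params$dt, params$gamma, params$kT,
                          as.integer(n_steps), as.double(params$seed),
                          state$step_count, as.integer(record_stride),
                          if (is.finite(params$force_cap)) params$force_cap else -1,
                          params$neighbor_skin)
  out <- state
  out$positions <- res$pos
  out$images <- res$img
  out$velocities <- res$vel
  out$step_count <- res$step_count
  out$time <- state$time + n_steps * params$dt
  if (record_stride > 0) {
    nrec <- dim(res$frames)[1]
    attr(out, "trajectory") <- new_trajectory(
      frames = res$frames,
      times = state$time + res$times - state$step_count * params$dt,
      box = state$box, topology = state$topology,
      pe = res$rec_pe, ke = res$rec_ke)
  }
  out
}

#' Switch interaction strengths mid-run
#'
#' Replaces the model's interaction table (positions and velocities are
#' untouched) and logs the switch time in the state's schedule. This is how
#' "temperature" protocols are realised: with T* = 1 fixed, rescaling the
#' well depths is equivalent to changing the real temperature.
#'
#' @param state A `simulation_state`.
#' @param model The current `cg_model`.
#' @param new_table An `interaction_table` for the same role structure.
#' @return List with the updated `state` (schedule logged) and `model`.
#' @export
switch_interactions <- function(state, model, new_table) {
  stopifnot(inherits(new_table, "interaction_table"))
  model$interactions <- new_table
  state$schedule <- c(state$schedule,
                      list(list(time = state$time, eps_D = new_table$eps_D,
                                eps_S = new_table$eps_S)))
  list(state = state, model = model)
}

.CHECKPOINT_VERSION <- 1L

#' Checkpointing
#'
#' Writes/restores the full simulation state (including image counts and the
#' reproducibility token, i.e. the global step counter) so that a run split
#' across a checkpoint is bit-identical to an unsplit run. Files are versioned
#' R serializations; a version mismatch or corrupted file raises an error
#' rather than returning partial state.
#'
#' @param state A `simulation_state`.
#' @param path File path.
#' @return `read_checkpoint` returns the restored `simulation_state`.
#' @export
write_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "simulation_state"))
  obj <- list(version = .CHECKPOINT_VERSION, state = state)
  tmp <- paste0(path, ".tmp")
  saveRDS(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable checkpoint: ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$version))
    stop("not an agedrop checkpoint file")
  if (obj$version != .CHECKPOINT_VERSION)
    stop("checkpoint version mismatch: file ", obj$version, ", supported ",
         .CHECKPOINT_VERSION)
  obj$state
}
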