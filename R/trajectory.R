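# Trajectory container: time-ordered unwrapped frames plus chain topology.

#' Construct a trajectory
#'
#' Frames are stored unwrapped (analysis such as mean-square displacement
#' needs true displacements); writers wrap coordinates back into the box.
#'
#' @param frames numeric array (n_frames x n_beads_total x 3), unwrapped.
#' @param times Frame times (tau*).
#' @param box Length-3 box vector (sigma).
#' @param topology List with `n_chains`, `n_beads`, `sequence`.
#' @param pe,ke Optional per-frame potential / kinetic energy traces.
#' @return An object of class `cg_trajectory`.
#' @export
new_trajectory <- function(frames, times, box, topology, pe = NULL, ke = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3,
            dim(frames)[1] == length(times))
  structure(list(frames = frames, times = as.numeric(times),
                 box = as.numeric(box), topology = topology,
                 pe = pe, ke = ke),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", n_frames(x), "frames,",
      x$topology$n_chains, "chains x", x$topology$n_beads, "beads, t in [",
      signif(min(x$times), 4), ",", signif(max(x$times), 4), "] tau*\n")
  invisible(x)
}

#' @rdname new_trajectory
#' @param traj A `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame
#' @param traj A `cg_trajectory`.
#' @param i Frame index.
#' @return n x 3 matrix of unwrapped positions.
#' @export
frame_positions <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$frames[i, , ], ncol = 3)
}

#' Concatenate trajectories (same topology and box)
#' @param ... `cg_trajectory` objects in time order.
#' @return A single `cg_trajectory`.
#' @export
concat_trajectories <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "cg_trajectory")) parts <- parts[[1]]
  parts <- Filter(function(p) !is.null(p) && n_frames(p) > 0, parts)
  stopifnot(length(parts) >= 1)
  n <- dim(parts[[1]]$frames)[2]
  frames <- do.call(rbind, lapply(parts, function(p) {
    matrix(p$frames, nrow = dim(p$frames)[1])
  }))
  frames <- array(frames, c(nrow(frames), n, 3))
  new_trajectory(frames,
                 times = unlist(lapply(parts, `[[`, "times")),
                 box = parts[[1]]$box, topology = parts[[1]]$topology,
                 pe = unlist(lapply(parts, function(p) p$pe %||% rep(NA_real_, n_frames(p)))),
                 ke = unlist(lapply(parts, function(p) p$ke %||% rep(NA_real_, n_frames(p)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# indices (1-based) of the central bead of each chain
.central_bead_idx <- function(topology) {
  nb <- topology$n_beads
  central <- (nb + 1L) %/% 2L
  (seq_len(topology$n_chains) - 1L) * nb + central
}

# wrap an n x 3 matrix into [0, L)
.wrap_positions <- function(pos, box) {
  sweep(pos, 2, box, function(p, L) p - L * floor(p / L))
}
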