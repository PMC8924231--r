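#' @useDynLib agedrop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm rnorm runif optimize
#' @importFrom utils head tail write.csv read.csv
NULL

# Bead roles. Integer codes are what the engine sees: 0 = stickerA,
# 1 = stickerB, 2 = spacer.
.ROLES <- c("stickerA", "stickerB", "spacer")

#' Bead role codes
#'
#' Three bead roles exist: `stickerA` and `stickerB` are the complementary
#' strongly binding segments, `spacer` the weakly binding background. Roles
#' are represented as character labels at the user level and as integer codes
#' (0, 1, 2) inside the engine.
#'
#' @return Character vector of the three role labels.
#' @export
bead_roles <- function() .ROLES

.role_code <- function(role) {
  m <- match(role, .ROLES)
  if (anyNA(m)) stop("unknown bead role(s): ", paste(role[is.na(m)], collapse = ", "))
  m - 1L
}

#' Reduced simulation units
#'
#' The model works in reduced units: bead diameter `sigma` as the length unit,
#' a reference energy `epsilon_ref` equal to kBT at the simulation
#' temperature, bead mass `mass`, and the derived time unit
#' `tau_star = sigma * sqrt(mass / epsilon_ref)`. With all three at 1 (the
#' default), energies are read directly in kBT and T* = 1; changing the
#' interaction strengths plays the role of changing temperature.
#'
#' @param sigma Bead diameter (length unit).
#' @param epsilon_ref Reference energy (kBT at the reference temperature).
#' @param mass Bead mass.
#' @return An object of class `reduced_units`.
#' @export
reduced_units <- function(sigma = 1, epsilon_ref = 1, mass = 1) {
  stopifnot(sigma > 0, epsilon_ref > 0, mass > 0)
  structure(list(sigma = sigma, epsilon_ref = epsilon_ref, mass = mass,
                 tau_star = sigma * sqrt(mass / epsilon_ref)),
            class = "reduced_units")
}

#' Build a sticker-spacer protein sequence
#'
#' Each chain is a linear bead-spring polymer of `n_beads` beads (39 by
#' default) carrying 3 stickers of type A, 2 of type B and 34 spacers for the
#' sticker-bearing patternings. `"uniform"` spreads the five stickers over the
#' full chain, `"half_chain"` packs all five into the first half, and
#' `"homopolymer"` is the all-spacer control in which every bead binds every
#' other with the same weak strength.
#'
#' @param patterning One of `"uniform"`, `"half_chain"`, `"homopolymer"`.
#' @param n_beads Number of beads per chain.
#' @param sticker_A,sticker_B 1-based indices of the A and B stickers;
#'   defaults depend on the patterning.
#' @return An object of class `protein_sequence` with fields `roles`
#'   (character vector), `n_beads` and `patterning`.
#' @examples
#' seqs <- make_sequence("uniform")
#' table(seqs$roles)
#' @export
make_sequence <- function(patterning = c("uniform", "half_chain", "homopolymer"),
                          n_beads = 39L, sticker_A = NULL, sticker_B = NULL) {
  patterning <- match.arg(patterning)
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 1L)
  roles <- rep("spacer", n_beads)
  if (patterning != "homopolymer") {
    if (is.null(sticker_A))
      sticker_A <- if (patterning == "uniform") c(5L, 19L, 33L) else c(3L, 11L, 19L)
    if (is.null(sticker_B))
      sticker_B <- if (patterning == "uniform") c(12L, 26L) else c(7L, 15L)
    sticker_A <- as.integer(sticker_A); sticker_B <- as.integer(sticker_B)
    all_idx <- c(sticker_A, sticker_B)
    if (anyDuplicated(all_idx))
      stop("sticker positions overlap")
    if (any(all_idx < 1L | all_idx > n_beads))
      stop("sticker positions out of range 1..", n_beads)
    if (patterning == "half_chain" && any(all_idx > n_beads %/% 2))
      stop("half_chain patterning requires all sticker indices in the first half")
    roles[sticker_A] <- "stickerA"
    roles[sticker_B] <- "stickerB"
  }
  structure(list(roles = roles, n_beads = n_beads, patterning = patterning),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$patterning, ", ", x$n_beads, " beads (",
      sum(x$roles == "stickerA"), " A, ", sum(x$roles == "stickerB"), " B, ",
      sum(x$roles == "spacer"), " spacer)\n", sep = "")
  invisible(x)
}

#' Interaction-strength table
#'
#' Symmetric well-depth lookup over role pairs. Complementary
#' stickerA-stickerB pairs bind with the strong well depth `eps_S`; every
#' other pair (spacer-spacer, spacer-sticker and homotypic sticker-sticker)
#' binds weakly with `eps_D`. By default the two are coupled as
#' `eps_S = 10 * eps_D`, so a single knob controls the overall interaction
#' scale; pass both explicitly to decouple them.
#'
#' @param eps_D Weak well depth (kBT). Required.
#' @param eps_S Strong well depth (kBT); default `10 * eps_D`.
#' @return An object of class `interaction_table` carrying the 3x3 matrix of
#'   well depths (role order stickerA, stickerB, spacer).
#' @examples
#' tab <- build_interaction_table(0.5)
#' well_depth(tab, "stickerA", "stickerB")  # 5
#' @export
build_interaction_table <- function(eps_D, eps_S = 10 * eps_D) {
  if (!is.finite(eps_D) || eps_D <= 0) stop("eps_D must be positive")
  if (!is.finite(eps_S) || eps_S <= 0) stop("eps_S must be positive")
  if (eps_S < eps_D) stop("eps_S must be >= eps_D")
  m <- matrix(eps_D, 3, 3, dimnames = list(.ROLES, .ROLES))
  m["stickerA", "stickerB"] <- eps_S
  m["stickerB", "stickerA"] <- eps_S
  structure(list(eps_D = eps_D, eps_S = eps_S, matrix = m),
            class = "interaction_table")
}

#' @rdname build_interaction_table
#' @param table An `interaction_table`.
#' @param role_i,role_j Role labels.
#' @export
well_depth <- function(table, role_i, role_j) {
  stopifnot(inherits(table, "interaction_table"))
  table$matrix[cbind(.role_code(role_i) + 1L, .role_code(role_j) + 1L)]
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> eps_D =", x$eps_D, "kBT, eps_S =", x$eps_S, "kBT",
      if (isTRUE(all.equal(x$eps_S, 10 * x$eps_D))) "(coupled eps_S = 10 eps_D)",
      "\n")
  invisible(x)
}

#' Nonbonded pair potential specification
#'
#' Two short-ranged attractive pair potentials are available. The
#' Lennard-Jones form (default, cutoff 3.0 sigma, energy-shifted to zero at
#' the cutoff) represents the associative interactions between beads. The
#' Wang-Frenkel form (mu = nu = 1, cutoff 1.5 sigma) is an exactly
#' finite-ranged alternative whose attraction range is much shorter; it
#' vanishes with zero slope at its cutoff, so no shift is needed.
#'
#' @param form `"lennard_jones"` or `"wang_frenkel"`.
#' @param cutoff Interaction cutoff in sigma; defaults 3.0 (LJ) / 1.5 (WF).
#' @param shift Shift the energy to zero at the cutoff (LJ only).
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(form = c("lennard_jones", "wang_frenkel"),
                           cutoff = NULL, shift = TRUE) {
  form <- match.arg(form)
  if (is.null(cutoff)) cutoff <- if (form == "lennard_jones") 3.0 else 1.5
  if (cutoff <= 2^(1 / 6)) stop("cutoff must exceed 2^(1/6) sigma")
  structure(list(form = form, cutoff = cutoff,
                 shift = isTRUE(shift) && form == "lennard_jones"),
            class = "potential_spec")
}

#' Harmonic bond specification
#'
#' Consecutive beads along a chain are connected by harmonic springs
#' `E(r) = k/2 (r - r0)^2`. The default spring constant (100 epsilon/sigma^2)
#' keeps bond-length fluctuations near 0.1 sigma at T* = 1 while remaining
#' stable at the default timestep.
#'
#' @param k_bond Spring constant (energy / sigma^2).
#' @param r0 Equilibrium bond length (sigma).
#' @return An object of class `bond_spec`.
#' @export
bond_spec <- function(k_bond = 100, r0 = 1) {
  stopifnot(k_bond > 0, r0 > 0)
  structure(list(k_bond = k_bond, r0 = r0), class = "bond_spec")
}

.wf_alpha <- function(rc, sigma) {
  rs2 <- (rc / sigma)^2
  2 * rs2 * (3 / (2 * (rs2 - 1)))^3
}

#' Pair potential energy
#'
#' Evaluates the nonbonded pair energy for a given separation and well depth.
#' For the (optionally shifted) Lennard-Jones form the unshifted minimum is
#' `-eps` at `r = 2^(1/6) sigma`; for the Wang-Frenkel form the prefactor is
#' chosen so the well depth is exactly `-eps` at its own minimum. Energies are
#' zero at and beyond the cutoff.
#'
#' @param spec A `potential_spec`.
#' @param r Separation(s), sigma units; must be positive.
#' @param eps Well depth (kBT).
#' @param sigma Bead diameter.
#' @return Energy (kBT), vectorised over `r`.
#' @export
pair_energy <- function(spec, r, eps, sigma = 1) {
  stopifnot(inherits(spec, "potential_spec"))
  if (any(r <= 0)) stop("pair separation must be positive")
  out <- numeric(length(r))
  inside <- r < spec$cutoff
  ri <- r[inside]
  if (spec$form == "lennard_jones") {
    sr6 <- (sigma / ri)^6
    e <- 4 * eps * (sr6^2 - sr6)
    if (spec$shift) {
      src6 <- (sigma / spec$cutoff)^6
      e <- e - 4 * eps * (src6^2 - src6)
    }
  } else {
    a <- .wf_alpha(spec$cutoff, sigma)
    s2 <- (sigma / ri)^2
    c2 <- (spec$cutoff / ri)^2
    e <- eps * a * (s2 - 1) * (c2 - 1)^2
  }
  out[inside] <- e
  out
}

#' Pair force
#'
#' Analytic gradient of [pair_energy()]: returns the force on particle i at
#' separation vector `r_vec = x_i - x_j`. Antisymmetric under particle
#' exchange and zero at and beyond the cutoff.
#'
#' @param spec A `potential_spec`.
#' @param r_vec Separation vector (length 3), `x_i - x_j`.
#' @inheritParams pair_energy
#' @return Force vector on particle i (energy / sigma).
#' @export
pair_force <- function(spec, r_vec, eps, sigma = 1) {
  stopifnot(inherits(spec, "potential_spec"), length(r_vec) == 3)
  r2 <- sum(r_vec^2)
  if (r2 <= 0) stop("zero separation: pair force diverges")
  if (r2 >= spec$cutoff^2) return(c(0, 0, 0))
  if (spec$form == "lennard_jones") {
    sr2 <- sigma^2 / r2
    sr6 <- sr2^3
    fr <- 24 * eps * (2 * sr6^2 - sr6) / r2
  } else {
    a <- .wf_alpha(spec$cutoff, sigma)
    s2 <- sigma^2 / r2
    c2 <- spec$cutoff^2 / r2
    fr <- 2 * eps * a * (s2 * (c2 - 1)^2 + 2 * (s2 - 1) * (c2 - 1) * c2) / r2
  }
  fr * r_vec
}

#' Harmonic bond energy
#'
#' @param spec A `bond_spec`.
#' @param r Bond length(s), sigma units.
#' @return Energy `k/2 (r - r0)^2`, vectorised over `r`.
#' @export
bond_energy <- function(spec, r) {
  stopifnot(inherits(spec, "bond_spec"), all(r >= 0))
  0.5 * spec$k_bond * (r - spec$r0)^2
}

#' Assemble a coarse-grained model
#'
#' Bundles a chain sequence, interaction table, pair potential and bond
#' specification into the model object consumed by the engine, builders and
#' protocols. Bonded 1-2 pairs are excluded from nonbonded interactions.
#'
#' @param sequence A `protein_sequence`.
#' @param interactions An `interaction_table`.
#' @param potential A `potential_spec`.
#' @param bonds A `bond_spec`.
#' @param units A `reduced_units`.
#' @return An object of class `cg_model`.
#' @examples
#' mod <- cg_model(make_sequence("uniform"), build_interaction_table(0.5))
#' @export
cg_model <- function(sequence, interactions,
                     potential = potential_spec(), bonds = bond_spec(),
                     units = reduced_units()) {
  stopifnot(inherits(sequence, "protein_sequence"),
            inherits(interactions, "interaction_table"),
            inherits(potential, "potential_spec"),
            inherits(bonds, "bond_spec"))
  structure(list(sequence = sequence, interactions = interactions,
                 potential = potential, bonds = bonds, units = units),
            class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat("<cg_model>\n")
  print(x$sequence)
  print(x$interactions)
  cat("  potential:", x$potential$form, "cutoff", x$potential$cutoff, "sigma",
      if (x$potential$shift) "(shifted)", "\n")
  cat("  bonds: k =", x$bonds$k_bond, "r0 =", x$bonds$r0, "\n")
  invisible(x)
}

# engine-facing encodings ----------------------------------------------------

.model_form_code <- function(model)
  if (model$potential$form == "lennard_jones") 0L else 1L

.model_eps_matrix <- function(model) model$interactions$matrix

# per-bead integer role codes for n_chains copies of the sequence
.topology_types <- function(sequence, n_chains) {
  rep.int(.role_code(sequence$roles), n_chains)
}

# bond list (0-based, m x 2) for n_chains linear chains
.topology_bonds <- function(n_beads, n_chains) {
  per <- cbind(seq_len(n_beads - 1L) - 1L, seq_len(n_beads - 1L))
  off <- rep((seq_len(n_chains) - 1L) * n_beads, each = n_beads - 1L)
  m <- per[rep(seq_len(n_beads - 1L), n_chains), , drop = FALSE] + off
  storage.mode(m) <- "integer"
  m
}
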