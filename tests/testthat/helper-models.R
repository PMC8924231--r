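# Shared fixtures built in code.

hetero_model <- function(eps_S = 5, ...) {
  cg_model(make_sequence("uniform"),
           build_interaction_table(eps_S / 10, eps_S), ...)
}

homo_model <- function(eps_D = 0.66, ...) {
  cg_model(make_sequence("homopolymer"),
           build_interaction_table(eps_D, eps_D), ...)
}

# n independent single-bead chains in a cubic box
free_bead_state <- function(n, edge, seed = 1) {
  seqn <- make_sequence("homopolymer", 1L)
  set.seed(seed)
  pos <- matrix(runif(n * 3) * edge, n, 3)
  simulation_state(pos, rep(edge, 3), seqn, n)
}

# model with no nonbonded interactions at all (ideal-chain limit; a tiny
# nonzero epsilon would still carry the r^-12 divergence when beads
# interpenetrate)
ideal_model <- function(n_beads = 39L) {
  seqn <- make_sequence("homopolymer", n_beads)
  m <- cg_model(seqn, build_interaction_table(1e-9, 1e-9))
  m$interactions$matrix[] <- 0
  m
}

# independent all-pairs contact-count oracle (no neighbor structures)
brute_strong_contacts <- function(pos, box, topology, cutoff) {
  roles <- rep(topology$sequence$roles, topology$n_chains)
  nb <- topology$n_beads
  chain_of <- (seq_len(nrow(pos)) - 1L) %/% nb + 1L
  count <- 0L
  edges <- NULL
  for (i in seq_len(nrow(pos) - 1)) {
    for (j in (i + 1):nrow(pos)) {
      if (chain_of[i] == chain_of[j]) next
      ab <- (roles[i] == "stickerA" && roles[j] == "stickerB") ||
            (roles[i] == "stickerB" && roles[j] == "stickerA")
      if (!ab) next
      dv <- pos[i, ] - pos[j, ]
      dv <- dv - box * round(dv / box)
      if (sum(dv^2) < cutoff^2) {
        count <- count + 1L
        edges <- rbind(edges, c(chain_of[i], chain_of[j]))
      }
    }
  }
  list(count = count, edges = edges)
}

# gyration-tensor oracle by direct double loop over coordinate pairs
brute_gyration_eigs <- function(pos) {
  n <- nrow(pos)
  S <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    s <- 0
    for (i in 1:n) for (j in 1:n)
      s <- s + (pos[i, a] - pos[j, a]) * (pos[i, b] - pos[j, b])
    S[a, b] <- s / (2 * n^2)
  }
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}
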