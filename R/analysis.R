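# Analysis module: every observable used by the maturation study.

# ---- clustering helpers ----------------------------------------------------

# connected components of the bead contact graph (distance < cutoff under
# minimum image); returns membership and the largest component's bead indices
.bead_clusters <- function(pos, box, cutoff) {
  n <- nrow(pos)
  prs <- cpp_neighbor_pairs(.wrap_positions(pos, box), box, cutoff)
  g <- igraph::graph_from_edgelist(prs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(membership = comp$membership, sizes = comp$csize)
}

.largest_cluster <- function(pos, box, cutoff) {
  cl <- .bead_clusters(pos, box, cutoff)
  big <- which.max(cl$sizes)
  list(members = which(cl$membership == big), membership = cl$membership,
       sizes = cl$sizes)
}

# mean local density of *inter-chain* packing over a cluster's beads: beads
# of other chains within `cutoff`, per search-sphere volume. Intra-chain
# neighbors are excluded - an isolated chain is self-dense, so counting them
# would make even a gas look condensed. Calibrated on reference states, the
# statistic is sharply bimodal: gas and dispersing systems score
# 0.02-0.03 beads/sigma^3, weak-liquid condensates 0.23-0.26; the
# condensed-phase gate used by the protocols is 0.12, half the weakest
# liquid reference. Robust both for compact droplets and for the
# percolating gas networks a radial profile cannot describe.
.local_density <- function(pos, box, members, topology, cutoff = 1.5) {
  nb <- topology$n_beads
  chain_of <- (seq_len(nrow(pos)) - 1L) %/% nb + 1L
  prs <- cpp_neighbor_pairs(.wrap_positions(pos, box), box, cutoff)
  inter <- chain_of[prs[, 1]] != chain_of[prs[, 2]]
  counts <- tabulate(c(prs[inter, 1], prs[inter, 2]), nbins = nrow(pos))
  mean(counts[members]) / (4 / 3 * pi * cutoff^3)
}

.CONDENSED_GATE <- 0.12

# per-axis circular mean recentring: shifts wrapped coordinates so a compact
# cluster sits contiguously around the box centre (diameter < box/2 assumed)
.recenter_cluster <- function(pos, box) {
  out <- .wrap_positions(pos, box)
  for (d in 1:3) {
    theta <- out[, d] / box[d] * 2 * pi
    mu <- atan2(mean(sin(theta)), mean(cos(theta))) / (2 * pi) * box[d]
    out[, d] <- out[, d] - mu
    out[, d] <- out[, d] - box[d] * round(out[, d] / box[d])
  }
  out
}

# fraction of each chain's beads inside the largest cluster; a chain belongs
# to the cluster if more than half its beads do
.chains_in_cluster <- function(members, topology) {
  nb <- topology$n_beads
  chain_of <- (seq_len(topology$n_chains * nb) - 1L) %/% nb + 1L
  counts <- tabulate(chain_of[members], nbins = topology$n_chains)
  which(counts > nb / 2)
}

#' Largest-cluster chain fraction of a frame
#'
#' @param pos n x 3 positions (wrapped or unwrapped).
#' @param box Box vector.
#' @param topology Chain topology list.
#' @param cutoff Bead-graph contact cutoff (sigma).
#' @return Fraction of chains belonging to the largest bead cluster.
#' @export
largest_cluster_fraction <- function(pos, box, topology, cutoff = 1.5) {
  cl <- .largest_cluster(pos, box, cutoff)
  length(.chains_in_cluster(cl$members, topology)) / topology$n_chains
}

# ---- diffusion -------------------------------------------------------------

# time-origin-averaged MSD of the given bead rows over frames [i0, i1]
.window_msd <- function(X, i0, i1, lags) {
  # X: nf x m x 3 array of unwrapped positions
  vapply(lags, function(l) {
    orig <- i0:(i1 - l)
    d <- X[orig + l, , , drop = FALSE] - X[orig, , , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
  }, numeric(1))
}

#' Windowed diffusion coefficient from central-bead MSD
#'
#' Estimates the protein diffusion coefficient D as a function of time from
#' the mean-square displacement of the central bead of each chain. The
#' trajectory is split into consecutive windows; each window is expanded
#' until the root MSD at its largest lag reaches `displacement_factor` bead
#' diameters (slowing dynamics therefore produce progressively longer
#' windows), and D is the slope/6 of a linear fit of MSD against lag over the
#' diffusive tail (lags in the upper half of the window).
#'
#' @param traj A `cg_trajectory` with uniform frame spacing.
#' @param displacement_factor Required central-bead displacement per window,
#'   in sigma (the sampling rule uses 3-5; default 4).
#' @param min_window Minimum window length in frames.
#' @param fit `"slope"` (linear fit over the diffusive tail, default) or
#'   `"endpoint"` (MSD(span)/(6 span)).
#' @param allow_partial Emit a final, flagged window even if the displacement
#'   rule could not be met before the trajectory ended (needed to quantify
#'   arrested systems, whose beads never travel far enough).
#' @param chains Optional chain indices to restrict the estimate to (e.g.
#'   the chains inside a condensate); default all chains.
#' @param remove_com Subtract the per-frame centre of mass of the selected
#'   central beads before computing displacements. For chains inside a small
#'   droplet this isolates internal mobility from the droplet's own
#'   rigid-body diffusion (which would otherwise put a floor of
#'   kT/(M N gamma) under D); irrelevant for bulk boxes.
#' @return A `diffusion_series` data frame with columns `window_center`,
#'   `D`, `span`, `displacement` and `displacement_ok`.
#' @export
msd_windowed <- function(traj, displacement_factor = 4, min_window = 8L,
                         fit = c("slope", "endpoint"), allow_partial = FALSE,
                         chains = NULL, remove_com = FALSE) {
  fit <- match.arg(fit)
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- n_frames(traj)
  if (nf < min_window + 1)
    stop("trajectory too short: need at least ", min_window + 1, " frames")
  dtf <- diff(traj$times)
  if (max(dtf) - min(dtf) > 1e-6 * max(dtf))
    stop("msd_windowed requires uniform frame spacing")
  dtf <- dtf[1]
  idx <- .central_bead_idx(traj$topology)
  if (!is.null(chains)) idx <- idx[chains]
  X <- traj$frames[, idx, , drop = FALSE]
  if (isTRUE(remove_com))
    for (d in 1:3) X[, , d] <- X[, , d] - rowMeans(X[, , d, drop = FALSE])
  sigma <- 1
  target2 <- (displacement_factor * sigma)^2

  rows <- list()
  s <- 1L
  while (s + min_window <= nf) {
    w <- min_window
    repeat {
      msd_end <- .window_msd(X, s, s + w, w)
      if (msd_end >= target2 || s + ceiling(w * 1.6) > nf) break
      w <- ceiling(w * 1.6)
    }
    met <- msd_end >= target2
    if (!met && !allow_partial) break
    lags <- unique(pmax(1L, round(seq(w / 2, w, length.out = min(16, w)))))
    msd <- .window_msd(X, s, s + w, lags)
    D <- if (fit == "slope" && length(lags) >= 2) {
      max(coef(lm(msd ~ I(lags * dtf)))[2] / 6, 0)
    } else {
      msd[length(msd)] / (6 * lags[length(lags)] * dtf)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      window_center = traj$times[s] + w * dtf / 2,
      D = D, span = w * dtf, displacement = sqrt(msd_end),
      displacement_ok = met)
    s <- s + w
    if (!met) break
  }
  if (!length(rows))
    stop("no valid diffusion window: central beads never displaced ",
         displacement_factor, " sigma (need a longer trajectory",
         if (!allow_partial) " or allow_partial = TRUE", ")")
  out <- do.call(rbind, rows)
  class(out) <- c("diffusion_series", "data.frame")
  attr(out, "displacement_factor") <- displacement_factor
  out
}

#' Classify a diffusion series as liquid or ageing
#'
#' Applies the kinetic threshold separating ergodic liquid-like behaviour
#' from ageing on the observation window: a series is liquid when its
#' terminal D sits above the threshold and has plateaued (relative change
#' below `plateau_tol` over the last `k` windows); otherwise it is ageing -
#' either D has already crossed below the threshold (onset time at the first
#' crossing) or it is still decaying monotonically towards it (onset `NA`,
#' flagged low-confidence).
#'
#' @param series A `diffusion_series`.
#' @param threshold Kinetic threshold (sigma^2/tau*). The default 2e-4 is 10
#'   percent of the weak-binding homopolymer liquid plateau (~2e-3).
#' @param plateau_tol Maximum relative change of D across the last `k`
#'   windows for the plateau test.
#' @param k Number of terminal windows used in the plateau test.
#' @return A `regime_label` list with `label` (`"liquid"`/`"ageing"`),
#'   `onset_time` (ageing only), `threshold_used` and `low_confidence`.
#' @export
classify_regime <- function(series, threshold = 2e-4, plateau_tol = 0.15,
                            k = 3L) {
  stopifnot(inherits(series, "diffusion_series") || is.data.frame(series))
  n <- nrow(series)
  D <- series$D
  terminal_above <- D[n] >= threshold
  kk <- min(k, n)
  tailD <- D[(n - kk + 1):n]
  plateaued <- n >= 3 &&
    (max(tailD) - min(tailD)) <= plateau_tol * max(max(tailD), .Machine$double.eps)
  still_decaying <- n >= 3 && tailD[kk] < tailD[1]
  below <- which(D < threshold)
  if (terminal_above && (plateaued || !still_decaying)) {
    # noisy series straddling the threshold: judged by the terminal plateau,
    # flagged low-confidence
    lab <- list(label = "liquid", onset_time = NA_real_,
                threshold_used = threshold,
                low_confidence = !plateaued || length(below) > 0)
  } else {
    onset <- if (length(below)) series$window_center[below[1]] else NA_real_
    lab <- list(label = "ageing", onset_time = onset,
                threshold_used = threshold,
                low_confidence = n < 3 || !length(below))
  }
  class(lab) <- "regime_label"
  lab
}

#' @export
print.regime_label <- function(x, ...) {
  cat("<regime_label>", x$label,
      if (x$label == "ageing") paste0("(onset ", signif(x$onset_time, 4), " tau*)"),
      if (x$low_confidence) "[low confidence]", "\n")
  invisible(x)
}

# ---- contacts --------------------------------------------------------------

#' Count strong inter-chain sticker contacts
#'
#' Counts inter-chain complementary stickerA-stickerB pairs closer than
#' `contact_cutoff` (minimum image). Homotypic sticker pairs and intra-chain
#' pairs never count. Chains sharing at least one strong contact form the
#' strong-contact graph, whose connected components are returned as clusters.
#'
#' @param pos n x 3 bead positions.
#' @param box Box vector.
#' @param topology Chain topology list (roles come from its sequence).
#' @param contact_cutoff Contact distance (sigma); default 1.5 covers the
#'   attractive well.
#' @return List with `count`, `pairs` (bead index pairs) and
#'   `chain_clusters` (list of chain-index vectors, size > 1 components).
#' @export
strong_contacts <- function(pos, box, topology, contact_cutoff = 1.5) {
  types <- .topology_types(topology$sequence, topology$n_chains)
  nb <- topology$n_beads
  chain_of <- (seq_len(nrow(pos)) - 1L) %/% nb + 1L
  prs <- cpp_neighbor_pairs(.wrap_positions(pos, box), box, contact_cutoff)
  if (nrow(prs)) {
    t1 <- types[prs[, 1]]; t2 <- types[prs[, 2]]
    ab <- (t1 == 0L & t2 == 1L) | (t1 == 1L & t2 == 0L)
    inter <- chain_of[prs[, 1]] != chain_of[prs[, 2]]
    prs <- prs[ab & inter, , drop = FALSE]
  }
  clusters <- list()
  if (nrow(prs)) {
    edges <- unique(cbind(chain_of[prs[, 1]], chain_of[prs[, 2]]))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, topology$n_chains - igraph::vcount(g)))
    comp <- igraph::components(g)
    clusters <- Filter(function(v) length(v) > 1,
                       split(seq_len(topology$n_chains), comp$membership))
    names(clusters) <- NULL
  }
  list(count = nrow(prs), pairs = prs, chain_clusters = clusters)
}

#' Strong-contact time series in a condensate
#'
#' Evaluates [strong_contacts()] on every frame and normalises the
#' strong-contact density (contacts per unit condensate volume, volume taken
#' from the largest cluster's radial-profile equimolar radius) by the arrest
#' threshold density, giving the dimensionless maturation coordinate: values
#' above 1 indicate enough strong contacts to drive the condensate out of the
#' liquid regime.
#'
#' @param traj A `cg_trajectory`.
#' @param contact_cutoff Contact distance (sigma).
#' @param threshold_density Strong-contact density (contacts/sigma^3) at the
#'   liquid-to-ageing crossover, used for normalisation.
#' @return A `contact_series` data frame with columns `time`, `n_strong`,
#'   `volume` and `normalized`.
#' @export
contact_series <- function(traj, contact_cutoff = 1.5,
                           threshold_density = 0.01) {
  nf <- n_frames(traj)
  out <- data.frame(time = traj$times, n_strong = NA_real_,
                    volume = NA_real_, normalized = NA_real_)
  for (f in seq_len(nf)) {
    pos <- frame_positions(traj, f)
    sc <- strong_contacts(pos, traj$box, traj$topology, contact_cutoff)
    cd <- condensate_density(pos, traj$box, cluster_cutoff = contact_cutoff)
    out$n_strong[f] <- sc$count
    out$volume[f] <- cd$volume
    out$normalized[f] <- (sc$count / cd$volume) / threshold_density
  }
  class(out) <- c("contact_series", "data.frame")
  out
}

#' Inter-chain contact persistence
#'
#' Fraction of inter-chain bead contacts present at a reference frame that
#' are still present one lag later, averaged over reference frames. Liquid
#' condensates exchange neighbours on the diffusive timescale, so their
#' persistence decays low; kinetically arrested aggregates retain their
#' contacts - long-lived interactions are the microscopic signature of
#' arrest.
#'
#' @param traj A `cg_trajectory`.
#' @param lag Persistence lag (tau*).
#' @param contact_cutoff Contact distance (sigma).
#' @param chains Optional chain indices to restrict to.
#' @return Mean fraction of retained contacts (0 to 1); `NA` if no contacts.
#' @export
contact_persistence <- function(traj, lag, contact_cutoff = 1.5,
                                chains = NULL) {
  nf <- n_frames(traj)
  dtf <- traj$times[2] - traj$times[1]
  kl <- max(1L, round(lag / dtf))
  if (kl >= nf) stop("lag exceeds the trajectory span")
  nb <- traj$topology$n_beads
  chain_of <- (seq_len(dim(traj$frames)[2]) - 1L) %/% nb + 1L
  keep <- if (is.null(chains)) rep(TRUE, length(chain_of)) else
    chain_of %in% chains
  contacts_at <- function(f) {
    pos <- .wrap_positions(frame_positions(traj, f), traj$box)
    prs <- cpp_neighbor_pairs(pos, traj$box, contact_cutoff)
    inter <- chain_of[prs[, 1]] != chain_of[prs[, 2]] &
      keep[prs[, 1]] & keep[prs[, 2]]
    prs <- prs[inter, , drop = FALSE]
    prs[prs[, 1] > prs[, 2], ] <- prs[prs[, 1] > prs[, 2], 2:1]
    paste(prs[, 1], prs[, 2])
  }
  refs <- unique(round(seq(1, nf - kl, length.out = min(5, nf - kl))))
  vals <- vapply(refs, function(f) {
    a <- contacts_at(f)
    if (!length(a)) return(NA_real_)
    mean(a %in% contacts_at(f + kl))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# ---- density ---------------------------------------------------------------

#' Condensate density and radial profile
#'
#' Identifies the largest bead cluster, recentres it, and returns its radial
#' density profile about the centre of mass together with the core (plateau)
#' density. The condensate volume is the ball bounded by the equimolar radius
#' (where the profile falls to half the core value). Clusters of fewer than
#' 100 beads have no resolvable plateau; their density is reported over the
#' gyration-equivalent sphere and flagged.
#'
#' @param pos n x 3 bead positions.
#' @param box Box vector.
#' @param cluster_cutoff Bead-graph cutoff (sigma).
#' @param shell_width Radial bin width (sigma).
#' @return List with `density` (beads/sigma^3), `volume`, `radius`,
#'   `profile` (data frame `r`, `rho`), `n_beads` and `small_cluster` flag.
#' @export
condensate_density <- function(pos, box, cluster_cutoff = 1.5,
                               shell_width = 1.0) {
  cl <- .largest_cluster(pos, box, cluster_cutoff)
  p <- .recenter_cluster(pos[cl$members, , drop = FALSE], box)
  p <- sweep(p, 2, colMeans(p))
  r <- sqrt(rowSums(p^2))
  nb <- length(r)
  if (nb < 100) {
    rg2 <- mean(rowSums(p^2))
    Req <- sqrt(5 / 3 * max(rg2, 1e-12))
    vol <- 4 / 3 * pi * Req^3
    return(list(density = nb / vol, volume = vol, radius = Req,
                profile = data.frame(r = numeric(0), rho = numeric(0)),
                n_beads = nb, small_cluster = TRUE))
  }
  edges <- seq(0, max(r) + shell_width, by = shell_width)
  counts <- tabulate(findInterval(r, edges), nbins = length(edges) - 1)
  vols <- 4 / 3 * pi * diff(edges^3)
  rho <- counts / vols
  mid <- (head(edges, -1) + tail(edges, -1)) / 2
  core <- mean(rho[seq_len(min(3, length(rho)))])
  below <- which(rho < core / 2)
  Re <- if (length(below)) mid[below[1]] else max(r)
  core_sel <- mid <= max(0.7 * Re, mid[1])  # never an empty core region
  density <- sum(counts[core_sel]) / sum(vols[core_sel])
  list(density = density, volume = 4 / 3 * pi * Re^3, radius = Re,
       profile = data.frame(r = mid, rho = rho), n_beads = nb,
       small_cluster = FALSE)
}

# ---- shape -----------------------------------------------------------------

#' Gyration-tensor shape metrics
#'
#' Computes the gyration tensor about the centre of mass and the standard
#' shape descriptors: ordered eigenvalues, asphericity
#' `b = l1 - (l2 + l3)/2`, and the relative shape anisotropy
#' `kappa^2 = (b^2 + 3/4 c^2) / (l1+l2+l3)^2`, which is 0 for spherically
#' symmetric mass distributions and 1 for collinear ones.
#'
#' @param pos m x 3 positions of the cluster (already contiguous, i.e. not
#'   split across periodic boundaries).
#' @return A `shape_metrics` list with `gyration_eigenvalues` (decreasing),
#'   `asphericity`, `acylindricity`, `relative_shape_anisotropy`, `rg2` and a
#'   `reduced_rank` flag for fewer than 4 points.
#' @export
shape_metrics <- function(pos) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, nrow(pos) >= 1)
  centred <- sweep(pos, 2, colMeans(pos))
  S <- crossprod(centred) / nrow(pos)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  tr <- sum(ev)
  b <- ev[1] - (ev[2] + ev[3]) / 2
  cc <- ev[2] - ev[3]
  k2 <- if (tr > 0) (b^2 + 0.75 * cc^2) / tr^2 else 0
  structure(list(gyration_eigenvalues = ev, asphericity = b,
                 acylindricity = cc,
                 relative_shape_anisotropy = min(max(k2, 0), 1),
                 rg2 = tr, reduced_rank = nrow(pos) < 4),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat("<shape_metrics> kappa^2 =", signif(x$relative_shape_anisotropy, 4),
      " asphericity =", signif(x$asphericity, 4),
      " Rg =", signif(sqrt(x$rg2), 4), "\n")
  invisible(x)
}

#' Shape of the largest cluster in each frame
#'
#' @param traj A `cg_trajectory`.
#' @param cluster_cutoff Bead-graph cutoff (sigma).
#' @return Data frame with `time`, `kappa2`, `rg`, `cluster_fraction`.
#' @export
shape_series <- function(traj, cluster_cutoff = 1.5) {
  nf <- n_frames(traj)
  out <- data.frame(time = traj$times, kappa2 = NA_real_, rg = NA_real_,
                    cluster_fraction = NA_real_)
  for (f in seq_len(nf)) {
    pos <- frame_positions(traj, f)
    cl <- .largest_cluster(pos, traj$box, cluster_cutoff)
    p <- .recenter_cluster(pos[cl$members, , drop = FALSE], traj$box)
    sm <- shape_metrics(p)
    out$kappa2[f] <- sm$relative_shape_anisotropy
    out$rg[f] <- sqrt(sm$rg2)
    out$cluster_fraction[f] <-
      length(.chains_in_cluster(cl$members, traj$topology)) /
      traj$topology$n_chains
  }
  out
}

# ---- coalescence -----------------------------------------------------------

#' Coalescence time of a tangent droplet pair
#'
#' The coalescence time tau_c is the first time at which (a) the largest
#' cluster contains at least `merge_fraction` of the chains and (b) its
#' relative shape anisotropy stays below `sphericity_tol` for a dwell period
#' (`dwell_frac * censor_time`). Pairs that never satisfy the criterion are
#' censored at `censor_time`; evaporating systems (largest cluster below half
#' the chains) are labelled distinctly.
#'
#' @param traj A `cg_trajectory` starting from exactly two clusters.
#' @param sphericity_tol kappa^2 tolerance for "single spherical condensate".
#' @param censor_time Maximum observation time (tau*); defaults to the last
#'   frame time.
#' @param dwell_frac Dwell period as a fraction of `censor_time`.
#' @param merge_fraction Chain fraction required in the largest cluster.
#' @param cluster_cutoff Bead-graph cutoff (sigma).
#' @return A `coalescence_result` list with `tau_c`, `censored`,
#'   `censor_time`, `status` and the per-frame `criterion_series`.
#' @export
coalescence_time <- function(traj, sphericity_tol = 0.02, censor_time = NULL,
                             dwell_frac = 0.1, merge_fraction = 0.95,
                             cluster_cutoff = 1.5) {
  ser <- shape_series(traj, cluster_cutoff)
  if (is.null(censor_time)) censor_time <- max(traj$times)
  dwell <- dwell_frac * censor_time
  ok <- ser$cluster_fraction >= merge_fraction & ser$kappa2 < sphericity_tol
  status <- "censored"; tau_c <- NA_real_
  # evaporation: terminal largest cluster clearly below half the chains (a
  # never-merging tangent pair sits exactly at one half, hence the margin)
  terminal <- ser$cluster_fraction[max(1, nrow(ser) - 2):nrow(ser)]
  if (mean(terminal) < 0.45) {
    status <- "evaporated"
  } else {
    spacing <- if (nrow(ser) > 1) stats::median(diff(ser$time)) else dwell
    for (f in which(ok)) {
      t0 <- ser$time[f]
      t_need <- min(t0 + dwell, max(ser$time))
      in_dwell <- ser$time >= t0 & ser$time <= t_need + 1e-9
      # sustained through the dwell, observed to within one frame of its end
      if (all(ok[in_dwell]) &&
          max(ser$time[in_dwell]) >= t_need - spacing - 1e-9) {
        tau_c <- t0
        status <- "fused"
        break
      }
    }
  }
  structure(list(tau_c = tau_c, censored = status != "fused",
                 censor_time = censor_time, status = status,
                 criterion_series = ser),
            class = "coalescence_result")
}

#' @export
print.coalescence_result <- function(x, ...) {
  cat("<coalescence_result>", x$status,
      if (x$status == "fused") paste0("tau_c = ", signif(x$tau_c, 4), " tau*")
      else paste0("(censor time ", signif(x$censor_time, 4), " tau*)"), "\n")
  invisible(x)
}

# ---- border curve ----------------------------------------------------------

#' Kinetic border between coalescence and maturation
#'
#' For each interaction strength, intersects its diffusion curve with the
#' kinetic threshold: the onset time at which D(t) crosses below the
#' threshold is the lapse available before the condensate enters the ageing
#' regime. Liquid state points (no crossing) are excluded. The border is
#' monotone non-increasing in eps_S: stronger binding arrests earlier.
#'
#' @param series_list Named list of `diffusion_series`; names are eps_S
#'   values (kBT).
#' @param threshold Kinetic threshold (sigma^2/tau*).
#' @return Data frame with `eps_S`, `onset_time` and `label`, sorted by
#'   `eps_S`; liquid points carry `onset_time = NA` and are flagged.
#' @export
border_curve <- function(series_list, threshold = 2e-4) {
  stopifnot(length(series_list) >= 1, !is.null(names(series_list)))
  rows <- lapply(names(series_list), function(nm) {
    lab <- classify_regime(series_list[[nm]], threshold = threshold)
    data.frame(eps_S = as.numeric(nm),
               onset_time = if (lab$label == "ageing" &&
                                !is.na(lab$onset_time)) lab$onset_time
                            else NA_real_,
               label = lab$label)
  })
  out <- do.call(rbind, rows)
  out[order(out$eps_S), , drop = FALSE]
}

# ---- real units ------------------------------------------------------------

#' Protein diffusion time in real units
#'
#' Mean time for a protein with 3-D diffusion coefficient `D_real` to diffuse
#' a distance `L`, from the Einstein relation `t = L^2 / (6 D)`. With a
#' typical in-condensate diffusion coefficient of 1 um^2/s and a typical
#' condensate distance of 5 um this gives 25/6 ~ 4.2 s; a deceleration of
#' 2-3 orders of magnitude (as seen upon maturation) maps the same journey to
#' minutes-to-an-hour, which [deceleration_time()] computes.
#'
#' @param D_real Diffusion coefficient (um^2/s).
#' @param L Distance (um).
#' @return Time in seconds.
#' @examples
#' diffusion_time_real_units(1, 5)  # 25/6 s
#' @export
diffusion_time_real_units <- function(D_real, L) {
  stopifnot(D_real > 0, L >= 0)
  L^2 / (6 * D_real)
}

#' @rdname diffusion_time_real_units
#' @param t_liquid Liquid-state diffusion time (s).
#' @param orders Orders of magnitude of diffusion deceleration.
#' @export
deceleration_time <- function(t_liquid, orders) t_liquid * 10^orders
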