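# IO module: configuration files, trajectory formats, result export.
# Extended XYZ is the canonical interchange format (role labels in the
# species column, wrapped coordinates plus image flags); LAMMPS text dumps
# are supported for interoperability. All times are tau*, lengths sigma,
# energies kBT.

.CONFIG_KEYS <- list(
  model = c("patterning", "n_beads", "sticker_A", "sticker_B", "eps_D",
            "eps_S", "couple_eps", "potential", "cutoff", "shift", "k_bond",
            "r0"),
  engine = c("dt", "gamma", "kT", "seed", "neighbor_skin"),
  geometry = c("kind", "n_chains", "box", "density", "droplet_sizes"),
  protocol = c("driver", "eps_S_grid", "schedule", "duration", "censor_time",
               "threshold", "displacement_factor"),
  output = c("outdir", "formats", "stride"))

#' Load and validate a run configuration
#'
#' Reads a YAML (or single-document TOML-like key:value YAML) configuration
#' with blocks `model`, `engine`, `geometry`, `protocol` and `output`,
#' validates it against the known schema (unknown keys are rejected with
#' their paths), resolves defaults, and enforces the interaction coupling
#' rule: when `couple_eps` is enabled (the default), `eps_S` must equal
#' `10 * eps_D`; supplying an inconsistent pair is an error.
#'
#' @param path Path to the YAML config.
#' @return A `run_config` list with resolved `model` (a `cg_model`), `engine`
#'   (an `engine_params`), raw blocks, and a provenance hash.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (blk in names(raw)) {
    if (!blk %in% names(.CONFIG_KEYS))
      stop("unknown config block: ", blk)
    bad <- setdiff(names(raw[[blk]]), .CONFIG_KEYS[[blk]])
    if (length(bad))
      stop("unknown config key(s): ",
           paste0(blk, ".", bad, collapse = ", "))
  }
  m <- raw$model %||% list()
  patterning <- m$patterning %||% "uniform"
  couple <- m$couple_eps %||% TRUE
  eps_D <- m$eps_D
  eps_S <- m$eps_S
  if (is.null(eps_D) && is.null(eps_S))
    stop("config must set model.eps_D or model.eps_S")
  if (couple) {
    if (is.null(eps_D)) eps_D <- eps_S / 10
    if (is.null(eps_S)) eps_S <- 10 * eps_D
    if (abs(eps_S - 10 * eps_D) > 1e-9)
      stop("model.eps_S and model.eps_D violate the coupling rule ",
           "eps_S = 10 eps_D (set couple_eps: false to decouple)")
  } else {
    if (is.null(eps_D)) eps_D <- eps_S
    if (is.null(eps_S)) eps_S <- eps_D
  }
  if (patterning == "homopolymer") eps_S <- eps_D
  seqn <- make_sequence(patterning, m$n_beads %||% 39L,
                        sticker_A = m$sticker_A, sticker_B = m$sticker_B)
  pot <- potential_spec(m$potential %||% "lennard_jones",
                        cutoff = m$cutoff, shift = m$shift %||% TRUE)
  bonds <- bond_spec(m$k_bond %||% 100, m$r0 %||% 1)
  model <- cg_model(seqn, build_interaction_table(eps_D, eps_S), pot, bonds)
  e <- raw$engine %||% list()
  engine <- engine_params(dt = e$dt %||% .auto_dt(model),
                          gamma = e$gamma %||% 1.0, kT = e$kT %||% 1.0,
                          seed = e$seed %||% 1L,
                          neighbor_skin = e$neighbor_skin %||% 0.4)
  cfg <- list(model = model, engine = engine,
              geometry = raw$geometry %||% list(),
              protocol = raw$protocol %||% list(),
              output = raw$output %||% list(),
              raw = raw,
              hash = unname(tools::md5sum(path)))
  class(cfg) <- "run_config"
  cfg
}

# ---- extended XYZ ----------------------------------------------------------

.ROLE_SPECIES <- c(stickerA = "A", stickerB = "B", spacer = "S")

#' Write / read trajectories as extended XYZ
#'
#' One block per frame: atom count, a comment line holding
#' `Lattice="..." Properties=species:S:1:pos:R:3:image:I:3 Time=...`, then one
#' line per bead with the role species (A/B/S), wrapped coordinates and
#' periodic image flags, so unwrapped coordinates round-trip exactly to the
#' written precision.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @param digits Coordinate precision (decimal digits).
#' @return `read_xyz` returns a `cg_trajectory`.
#' @export
write_xyz <- function(traj, path, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$frames)[2]
  topo <- traj$topology
  species <- .ROLE_SPECIES[rep(topo$sequence$roles, topo$n_chains)]
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits,
                "f %d %d %d")
  for (f in seq_len(n_frames(traj))) {
    upos <- frame_positions(traj, f)
    img <- floor(sweep(upos, 2, traj$box, `/`))
    wpos <- upos - sweep(img, 2, traj$box, `*`)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.8f 0 0 0 %.8f 0 0 0 %.8f" Properties=species:S:1:pos:R:3:image:I:3 Time=%.8f',
      traj$box[1], traj$box[2], traj$box[3], traj$times[f]), con)
    writeLines(sprintf(fmt, species, wpos[, 1], wpos[, 2], wpos[, 3],
                       as.integer(img[, 1]), as.integer(img[, 2]),
                       as.integer(img[, 3])), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @param topology Optional topology; by default chains are reconstructed
#'   from the species pattern (each chain shares the written bead count and
#'   role sequence of the first frame's species column split evenly).
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  if (!length(lines))
    return(new_trajectory(array(0, c(0, 0, 3)), numeric(0), c(1, 1, 1),
                          topology %||% list(n_chains = 0L, n_beads = 0L,
                                             sequence = make_sequence("homopolymer", 1L))))
  frames <- list(); times <- numeric(0); box <- NULL; species <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ frame header at line ", i)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    if (is.na(lat)) stop("missing Lattice in XYZ comment at line ", i + 1L)
    lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    bx <- lv[c(1, 5, 9)]
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]][2]
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(parts) < 7)
    if (length(bad)) stop("malformed XYZ atom line at line ", i + 1L + bad[1])
    mat <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:7))), n, 6,
                  byrow = TRUE)
    if (is.null(species)) species <- vapply(parts, `[`, "", 1)
    upos <- mat[, 1:3] + sweep(mat[, 4:6, drop = FALSE], 2, bx, `*`)
    frames[[length(frames) + 1L]] <- upos
    times <- c(times, if (is.na(tm)) length(frames) - 1 else as.numeric(tm))
    box <- bx
    i <- i + 2L + n
  }
  n <- nrow(frames[[1]])
  if (is.null(topology)) {
    roles <- names(.ROLE_SPECIES)[match(species, .ROLE_SPECIES)]
    # reconstruct chains: the role pattern repeats every n_beads
    nb <- .detect_chain_length(roles)
    seqn <- make_sequence("homopolymer", nb)
    seqn$roles <- roles[seq_len(nb)]
    seqn$patterning <- if (all(seqn$roles == "spacer")) "homopolymer" else "uniform"
    topology <- list(n_chains = as.integer(n / nb), n_beads = nb,
                     sequence = seqn)
  }
  arr <- array(0, c(length(frames), n, 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  new_trajectory(arr, times, box, topology)
}

.detect_chain_length <- function(roles) {
  n <- length(roles)
  for (nb in seq_len(n)) {
    if (n %% nb == 0 &&
        all(roles == rep(roles[seq_len(nb)], n / nb))) return(nb)
  }
  n
}

# ---- LAMMPS dump -----------------------------------------------------------

#' Write / read trajectories as LAMMPS text dumps
#'
#' `ITEM: ATOMS id type x y z ix iy iz` with types 1 = stickerA,
#' 2 = stickerB, 3 = spacer. The reader tolerates permuted columns (it reads
#' the column names from the ATOMS header) and accepts `xs ys zs` scaled
#' coordinates.
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @return `read_lammps_dump` returns a `cg_trajectory`.
#' @export
write_lammps_dump <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- traj$topology
  types <- .topology_types(topo$sequence, topo$n_chains) + 1L
  n <- dim(traj$frames)[2]
  for (f in seq_len(n_frames(traj))) {
    upos <- frame_positions(traj, f)
    img <- floor(sweep(upos, 2, traj$box, `/`))
    wpos <- upos - sweep(img, 2, traj$box, `*`)
    writeLines(c("ITEM: TIMESTEP", format(traj$times[f], digits = 12),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0.0 %.8f", traj$box[1]),
                 sprintf("0.0 %.8f", traj$box[2]),
                 sprintf("0.0 %.8f", traj$box[3]),
                 "ITEM: ATOMS id type x y z ix iy iz"), con)
    writeLines(sprintf("%d %d %.8f %.8f %.8f %d %d %d", seq_len(n), types,
                       wpos[, 1], wpos[, 2], wpos[, 3],
                       as.integer(img[, 1]), as.integer(img[, 2]),
                       as.integer(img[, 3])), con)
  }
  invisible(path)
}

#' @rdname write_lammps_dump
#' @param topology Optional topology (defaults to independent 1-bead chains
#'   with roles from the type column).
#' @export
read_lammps_dump <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); box <- NULL; types <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("malformed dump at line ", i)
    tm <- as.numeric(lines[i + 1L])
    n <- as.integer(lines[i + 3L])
    b <- vapply(lines[i + 5:7], function(l)
      diff(as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])), numeric(1))
    lo <- vapply(lines[i + 5:7], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1]), numeric(1))
    hdr <- strsplit(trimws(sub("^ITEM: ATOMS\\s*", "", lines[i + 8L])),
                    "\\s+")[[1]]
    rows <- lines[(i + 9L):(i + 8L + n)]
    mat <- matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
                  n, length(hdr), byrow = TRUE)
    colnames(mat) <- hdr
    ord <- order(mat[, "id"])
    mat <- mat[ord, , drop = FALSE]
    if (all(c("x", "y", "z") %in% hdr)) {
      w <- mat[, c("x", "y", "z")] - matrix(lo, n, 3, byrow = TRUE)
    } else if (all(c("xs", "ys", "zs") %in% hdr)) {
      w <- sweep(mat[, c("xs", "ys", "zs")], 2, b, `*`)
    } else stop("dump has neither x y z nor xs ys zs columns")
    img <- if (all(c("ix", "iy", "iz") %in% hdr))
      mat[, c("ix", "iy", "iz")] else matrix(0, n, 3)
    frames[[length(frames) + 1L]] <- w + sweep(img, 2, b, `*`)
    times <- c(times, tm)
    box <- b
    if (is.null(types)) types <- as.integer(mat[, "type"])
    i <- i + 9L + n
  }
  if (is.null(topology)) {
    roles <- .ROLES[types]
    nb <- .detect_chain_length(roles)
    seqn <- make_sequence("homopolymer", nb)
    seqn$roles <- roles[seq_len(nb)]
    seqn$patterning <- if (all(seqn$roles == "spacer")) "homopolymer" else "uniform"
    topology <- list(n_chains = as.integer(nrow(frames[[1]]) / nb),
                     n_beads = nb, sequence = seqn)
  }
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  new_trajectory(arr, times, box, topology)
}

# ---- results export --------------------------------------------------------

.atomic_write <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp")
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Export experiment records
#'
#' Writes one JSON summary per record, tidy CSVs per observable class
#' (diffusion windows, shape frames, contact frames, coalescence cells; one
#' row per window/frame/cell, censored coalescence rows carry a flag
#' column), and a campaign manifest whose hash changes iff any record's
#' configuration changed. Writes are atomic (write to temporary, rename).
#'
#' @param records List of `experiment_record` (or a single one).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
export_results <- function(records, outdir) {
  if (inherits(records, "experiment_record")) records <- list(records)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(records)))
    names(records) <- sprintf("record_%03d", seq_along(records))
  diff_rows <- list(); shape_rows <- list(); contact_rows <- list()
  coal_rows <- list()
  for (nm in names(records)) {
    rec <- records[[nm]]
    summ <- list(protocol = rec$protocol, config = rec$config,
                 seed = rec$seed, schedule = rec$schedule,
                 labels = .jsonable(rec$labels), runtime = rec$runtime,
                 provenance = rec$provenance)
    .atomic_write(function(p) jsonlite::write_json(
      summ, p, auto_unbox = TRUE, digits = NA, null = "null",
      force = TRUE), file.path(outdir, paste0(nm, ".json")))
    s <- rec$series
    if (!is.null(s$diffusion))
      diff_rows[[nm]] <- cbind(record = nm, as.data.frame(s$diffusion))
    if (!is.null(s$shape))
      shape_rows[[nm]] <- cbind(record = nm, s$shape)
    if (!is.null(s$contacts))
      contact_rows[[nm]] <- cbind(record = nm, as.data.frame(s$contacts))
    cr <- rec$labels$result
    if (inherits(cr, "coalescence_result"))
      coal_rows[[nm]] <- data.frame(record = nm,
                                    size = rec$config$size %||% NA,
                                    eps_S = rec$config$eps_S %||% NA,
                                    tau_c = cr$tau_c,
                                    censored = cr$censored,
                                    status = cr$status)
  }
  wcsv <- function(rows, fname) {
    if (!length(rows)) return()
    .atomic_write(function(p)
      write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), p,
                row.names = FALSE),
      file.path(outdir, fname))
  }
  wcsv(diff_rows, "diffusion.csv")
  wcsv(shape_rows, "shape.csv")
  wcsv(contact_rows, "contacts.csv")
  wcsv(coal_rows, "coalescence.csv")
  manifest <- list(
    records = lapply(records, function(r)
      list(protocol = r$protocol, config = r$config, seed = r$seed)),
    files = list.files(outdir, pattern = "\\.(json|csv)$"))
  cfg_json <- jsonlite::toJSON(manifest$records, auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  mpath <- file.path(outdir, "manifest.json")
  .atomic_write(function(p) jsonlite::write_json(
    manifest, p, auto_unbox = TRUE, digits = NA, force = TRUE), mpath)
  invisible(mpath)
}

.jsonable <- function(x) {
  if (inherits(x, "regime_label") || inherits(x, "coalescence_result") ||
      inherits(x, "shape_metrics"))
    return(lapply(unclass(x)[!vapply(x, is.data.frame, TRUE)], .jsonable))
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}
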