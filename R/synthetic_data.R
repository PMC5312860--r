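# Surrogate data generation at two tiers.
#
# Langevin tier: the mononucleotide is a rigid 3-pseudo-atom cluster
# (phosphate / sugar / base) released above the pore and descending under a
# constant field-like drift plus isotropic diffusion (overdamped Langevin).
# It exercises the full pipeline: trajectories -> classification ->
# contacts -> statistics -> model fit.
#
# Bernoulli tier: per-run possible-capture outcomes drawn directly from a
# known linear truth model, giving exact statistical control for
# parameter-recovery studies.

SOLUTE_HALF_LENGTH <- 0.25  # nm, phosphate/base offset from the centre

#' Generator configuration for the Langevin tier
#'
#' Defaults are tuned so that capture fractions across the default
#' condition grid span roughly 10--90%.  The drift term plays the role of
#' the transmembrane field driving the nucleotide down; the orientation
#' bonus gives phosphate-down releases a slightly stronger pull, and the
#' sticky-site affinity emulates competing binding at the D45/K46/N47
#' sites on the cap surface.
#'
#' @param diffusion_coefficient nm^2/ns.
#' @param drift_speed downward drift, nm/ns.
#' @param orientation_drift_bonus extra drift (nm/ns) for phosphate-down.
#' @param timestep integration step, ps; must divide `frame_interval`.
#' @param duration trajectory length, ps.
#' @param frame_interval output interval, ps.
#' @param sticky_site_affinity per-step pause probability while resting on
#'   the cap annulus, in \[0, 1\].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(diffusion_coefficient = 0.4,
                             drift_speed = 0.3,
                             orientation_drift_bonus = 0.1,
                             timestep = 1,
                             duration = 5000,
                             frame_interval = 10,
                             sticky_site_affinity = 0.2) {
  if (diffusion_coefficient < 0 || drift_speed < 0 ||
      orientation_drift_bonus < 0)
    stop("rates must be non-negative")
  if (sticky_site_affinity < 0 || sticky_site_affinity > 1)
    stop("sticky_site_affinity must be in [0, 1]")
  if (timestep <= 0) stop("timestep must be positive")
  if (timestep > frame_interval)
    stop("timestep (", timestep, " ps) exceeds the frame interval (",
         frame_interval, " ps)")
  if (abs(frame_interval / timestep - round(frame_interval / timestep)) >
        1e-9)
    stop("timestep must divide the frame interval")
  structure(list(diffusion_coefficient = diffusion_coefficient,
                 drift_speed = drift_speed,
                 orientation_drift_bonus = orientation_drift_bonus,
                 timestep = timestep, duration = duration,
                 frame_interval = frame_interval,
                 sticky_site_affinity = sticky_site_affinity),
            class = "generator_config")
}

#' Release-point design grid
#'
#' The study design: on-axis releases at a series of heights above the K8
#' ring, plus lateral translations at one fixed height, each in both
#' phosphate orientations with independent replicates.  Defaults are the
#' 10/15/20/30/40 angstrom heights, 5/10/15/20 angstrom translations at 30
#' angstroms, and 20 replicates (360 runs).
#'
#' @param heights on-axis release heights, nm, strictly increasing.
#' @param translations lateral offsets, nm, strictly increasing.
#' @param translation_height fixed height of the displacement study, nm.
#' @param orientations phosphate orientations to include.
#' @param replicates independent runs per condition.
#' @return object of class `design_grid`.
#' @export
design_grid <- function(heights = c(1.0, 1.5, 2.0, 3.0, 4.0),
                        translations = c(0.5, 1.0, 1.5, 2.0),
                        translation_height = 3.0,
                        orientations = c("up", "down"),
                        replicates = 20) {
  if (length(heights) == 0L || any(heights <= 0) ||
      any(diff(heights) <= 0))
    stop("heights must be non-empty, positive and strictly increasing")
  if (length(translations) > 0L &&
      (any(translations <= 0) || any(diff(translations) <= 0)))
    stop("translations must be positive and strictly increasing")
  if (!all(orientations %in% c("up", "down")))
    stop("orientations must be 'up' and/or 'down'")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(heights = heights, translations = translations,
                 translation_height = translation_height,
                 orientations = orientations, replicates = replicates),
            class = "design_grid")
}

# Reproducible per-run seed from a master seed and row index (Lehmer-style
# mixing, kept below 2^31).
derive_seed <- function(master, index) {
  as.integer((48271 * (as.numeric(master) %% 2147483647) +
                30269 * index) %% 2147483647) + 1L
}

#' Enumerate the condition grid
#'
#' One row per (condition, orientation, replicate) in deterministic order:
#' on-axis heights first (translation 0), then the displacement series at
#' the fixed study height.  Per-run seeds are derived reproducibly from
#' the master seed.
#'
#' @param design a `design_grid`.
#' @param master_seed integer master seed.
#' @param duration run length, ps.
#' @return data.frame with columns `run`, `height`, `translation`,
#'   `orientation`, `replicate`, `duration`, `seed`.
#' @export
build_condition_grid <- function(design = design_grid(), master_seed = 1,
                                 duration = 5000) {
  conds <- rbind(
    data.frame(height = design$heights, translation = 0),
    if (length(design$translations))
      data.frame(height = design$translation_height,
                 translation = design$translations))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      orientation = design$orientations,
                      cond = seq_len(nrow(conds)),
                      stringsAsFactors = FALSE)
  out <- data.frame(run = seq_len(nrow(grid)),
                    height = conds$height[grid$cond],
                    translation = conds$translation[grid$cond],
                    orientation = grid$orientation,
                    replicate = grid$replicate,
                    duration = duration)
  out$seed <- derive_seed(master_seed, out$run)
  out
}

# Representative C-alpha placement (radial, axial; nm offsets scaled to the
# geometry) for the surrogate heptamer.  One ring of 7 per residue.
.SURROGATE_RESIDUES <- data.frame(
  resid = c("ASP", "SER", "THR", "ASP", "ASN",
            "ALA", "ASN", "LYS", "GLY", "THR", "GLY", "SER", "ASN",
            "THR", "THR", "VAL",
            "ASP", "LYS", "ASN"),
  resno = c(2L, 3L, 9L, 13L, 293L,
            1L, 6L, 8L, 10L, 11L, 15L, 16L, 17L,
            18L, 19L, 20L,
            45L, 46L, 47L),
  radial = c(0.85, 0.90, 1.05, 1.00, 0.70,
             1.35, 1.30, 1.00, 1.35, 1.30, 1.20, 1.15, 0.85,
             1.25, 1.30, 1.35,
             1.70, 1.90, 2.15),
  z = c(-1.00, -0.85, -0.30, -0.60, -1.20,
        -0.05, -0.10, 0.00, -0.15, -0.25, -0.40, -0.45, -0.50,
        -0.35, -0.20, -0.10,
        0.05, 0.05, 0.05),
  stringsAsFactors = FALSE)

#' Build the surrogate topology
#'
#' A heptamer of pseudo C-alpha atoms for the zoned residues (the K8 and
#' N17 rings taken from the geometry itself) plus a 3-pseudo-atom
#' mononucleotide (`P`, `SUG`, `BAS` in residue `CMP`).
#'
#' @param geometry a `pore_geometry`.
#' @return a `topology` whose `ref_coords` place the protein at its static
#'   positions and the solute at the origin.
#' @export
build_surrogate_topology <- function(geometry) {
  res <- .SURROGATE_RESIDUES
  # pin the reference rings to the geometry's planes/radii
  res$radial[res$resno == 8L] <- geometry$pore_mouth_radius
  res$z[res$resno == 8L] <- 0
  res$radial[res$resno == 17L] <-
    sqrt(sum((geometry$n17_ring$positions[1, 1:2])^2))
  res$z[res$resno == 17L] <- geometry$capture_plane_z

  n <- 7L
  chains <- LETTERS[seq_len(n)]
  prot <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    pos <- .heptagon(res$radial[i], res$z[i], n = n,
                     phase = 2 * pi * (i - 1) / (n * nrow(res)))
    data.frame(atom_name = "CA", element = "C", resid = res$resid[i],
               resno = res$resno[i], chain = chains,
               solute = FALSE, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               stringsAsFactors = FALSE)
  }))
  sol <- data.frame(atom_name = c("P", "SUG", "BAS"), element = c("P", "C", "N"),
                    resid = "CMP", resno = 1L, chain = "X", solute = TRUE,
                    x = 0, y = 0,
                    z = c(SOLUTE_HALF_LENGTH, 0, -SOLUTE_HALF_LENGTH),
                    stringsAsFactors = FALSE)
  all <- rbind(prot, sol)
  all$atom_id <- seq_len(nrow(all))
  topology(all[, c("atom_id", "atom_name", "element", "resid", "resno",
                   "chain", "solute")],
           ref_coords = as.matrix(all[, c("x", "y", "z")]))
}

# Axial offsets of the P/SUG/BAS pseudo-atoms for a given orientation:
# phosphate "down" points the phosphate at the pore.
.solute_offsets <- function(orientation) {
  s <- if (orientation == "down") -1 else 1
  c(P = s * SOLUTE_HALF_LENGTH, SUG = 0, BAS = -s * SOLUTE_HALF_LENGTH)
}

#' Simulate one surrogate trajectory
#'
#' Overdamped Langevin descent of the solute centre from the release point
#' (axial = height, radial = translation), with membrane/wall reflection,
#' sticky pauses on the cap annulus, and absorbing capture below the N17
#' plane (see the generator configuration for parameters).  Fully
#' reproducible from `condition$seed`.
#'
#' @param condition one-row data.frame (or list) with `height`,
#'   `translation`, `orientation`, `duration`, `seed`.
#' @param geometry a `pore_geometry`.
#' @param config a `generator_config`.
#' @param topology optional `topology` (defaults to the full surrogate
#'   topology; pass a smaller one to skip protein bookkeeping).
#' @return a `trajectory`; the generator's own capture record is attached
#'   as `attr(, "sim_truth")`.
#' @export
simulate_trajectory <- function(condition, geometry,
                                config = generator_config(),
                                topology = NULL) {
  stopifnot(inherits(geometry, "pore_geometry"),
            inherits(config, "generator_config"))
  if (is.null(topology)) topology <- build_surrogate_topology(geometry)
  cond <- as.list(condition)
  duration <- if (!is.null(cond$duration)) cond$duration else config$duration
  drift <- config$drift_speed +
    if (identical(cond$orientation, "down")) config$orientation_drift_bonus
    else 0
  n_steps <- as.integer(round(duration / config$timestep))
  stride <- as.integer(round(config$frame_interval / config$timestep))

  set.seed(cond$seed)
  path <- langevin_path_cpp(
    start = c(cond$translation, 0, cond$height),
    drift = drift, diffusion = config$diffusion_coefficient,
    dt_ps = config$timestep, n_steps = n_steps, frame_stride = stride,
    capture_plane_z = geometry$capture_plane_z,
    mouth_radius = geometry$pore_mouth_radius,
    cap_outer_radius = geometry$cap_outer_radius,
    barrel_exit_z = geometry$barrel_exit_z,
    sticky_affinity = config$sticky_site_affinity,
    zoff_lo = -SOLUTE_HALF_LENGTH, zoff_hi = SOLUTE_HALF_LENGTH)

  centres <- path$frames
  nf <- nrow(centres)
  ref <- attr(topology, "ref_coords")
  coords <- matrix(rep(as.vector(t(ref)), each = nf), nrow = nf)
  off <- .solute_offsets(cond$orientation)
  sol_rows <- which(topology$solute)
  for (i in sol_rows) {
    dz <- off[[topology$atom_name[i]]]
    if (is.null(dz)) dz <- 0
    coords[, 3 * i - 2] <- centres[, 1]
    coords[, 3 * i - 1] <- centres[, 2]
    coords[, 3 * i] <- centres[, 3] + dz
  }
  traj <- trajectory(topology, coords,
                     times = (seq_len(nf) - 1L) * config$frame_interval)
  attr(traj, "sim_truth") <- list(
    captured = path$captured,
    latch_time = if (is.na(path$latch_step)) NA_real_
                 else path$latch_step * config$timestep,
    translocated = path$translocated)
  traj
}

#' Draw Bernoulli capture outcomes from a truth model
#'
#' For each condition row, a possible-capture outcome is drawn from
#' `Bernoulli(clamp(p/100, 0, 1))` where `p` is the truth model's
#' prediction for that height/translation/orientation.  The resulting
#' labels are `possible` / `failed` (the Bernoulli tier addresses the
#' upper probability bound, captured + possible).
#'
#' @param truth_model a `capture_model`, or a named list with `up`/`down`
#'   entries.
#' @param conditions data.frame with `height`, `translation`,
#'   `orientation` columns (e.g. from [build_condition_grid()]).
#' @param seed integer seed for the draws.
#' @return `conditions` with added `p_truth` (%), `possible_capture`
#'   (logical) and `label` columns.
#' @export
sample_outcomes <- function(truth_model, conditions, seed = 1) {
  models <- if (inherits(truth_model, "capture_model"))
    list(up = truth_model, down = truth_model) else truth_model
  stopifnot(all(conditions$orientation %in% names(models)))
  p <- vapply(seq_len(nrow(conditions)), function(i) {
    m <- models[[conditions$orientation[i]]]
    as.numeric(predict(m, conditions$height[i], conditions$translation[i]))
  }, numeric(1))
  p01 <- pmin(pmax(p / 100, 0), 1)
  set.seed(seed)
  hit <- rbinom(nrow(conditions), 1L, p01) == 1L
  out <- conditions
  out$p_truth <- p
  out$possible_capture <- hit
  out$label <- ifelse(hit, "possible", "failed")
  out
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes a topology PDB, a manifest CSV, a metadata JSON recording every
#' parameter and seed, and — on the Langevin tier — one XYZ trajectory per
#' run, or — on the Bernoulli tier — an outcomes CSV.
#'
#' @param dir output directory (created if needed).
#' @param tier `"bernoulli"` or `"langevin"`.
#' @param design a `design_grid`.
#' @param geometry a `pore_geometry`.
#' @param config a `generator_config` (Langevin tier).
#' @param truth_model truth for the Bernoulli tier (default: the reference
#'   wild-type models).
#' @param master_seed integer master seed.
#' @return invisibly, the manifest data.frame (with `trajectory_path` or
#'   outcome columns filled in).
#' @export
generate_dataset <- function(dir, tier = c("bernoulli", "langevin"),
                             design = design_grid(),
                             geometry = build_default_pore(),
                             config = generator_config(),
                             truth_model = alpha_hemolysin_models(),
                             master_seed = 1) {
  tier <- match.arg(tier)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- build_condition_grid(design, master_seed,
                               duration = config$duration)
  top <- build_surrogate_topology(geometry)
  write_topology(top, file.path(dir, "topology.pdb"))

  if (tier == "bernoulli") {
    out <- sample_outcomes(truth_model, grid,
                           seed = derive_seed(master_seed, 0L))
    write.csv(out, file.path(dir, "outcomes.csv"), row.names = FALSE)
  } else {
    grid$trajectory_path <- sprintf("run_%04d.xyz", grid$run)
    for (i in seq_len(nrow(grid))) {
      traj <- simulate_trajectory(grid[i, ], geometry, config, top)
      write_trajectory(traj, file.path(dir, grid$trajectory_path[i]))
    }
    out <- grid
  }
  write_manifest(out, file.path(dir, "manifest.csv"))
  meta <- list(tier = tier, master_seed = master_seed,
               design = unclass(design), generator = unclass(config),
               geometry = list(pore_mouth_radius = geometry$pore_mouth_radius,
                               cap_outer_radius = geometry$cap_outer_radius,
                               capture_plane_z = geometry$capture_plane_z,
                               barrel_exit_z = geometry$barrel_exit_z),
               rng = "R Mersenne-Twister via set.seed(per-run seed)",
               package_version = as.character(utils::packageVersion("porecap")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
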