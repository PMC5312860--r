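# Trichotomous capture classification against the N17 C-alpha ring:
# captured (all solute atoms below the ring, inside the pore), failed (all
# above), possible capture (straddling).  Capture is latched: once the
# whole solute is below the ring inside the pore it is regarded as
# captured for good — across all runs no exit from the vestibule was
# observed once the solute interacted below this region, so later frames
# cannot revoke the label.

#' Classification configuration
#'
#' @param geometry a `pore_geometry` supplying the default planes/radii.
#' @param capture_plane_z axial position of the N17 ring, nm.
#' @param pore_mouth_radius radial bound for "inside the pore", nm.
#' @param translocation_plane_z barrel exit plane, nm.
#' @param evaluation `"latched"` (default: the first fully-below frame
#'   fixes the label) or `"final_frame"` (label from the last frame only).
#' @return object of class `classification_config`.
#' @export
classification_config <- function(geometry = build_default_pore(),
                                  capture_plane_z = geometry$capture_plane_z,
                                  pore_mouth_radius = geometry$pore_mouth_radius,
                                  translocation_plane_z = geometry$barrel_exit_z,
                                  evaluation = c("latched", "final_frame")) {
  evaluation <- match.arg(evaluation)
  if (translocation_plane_z >= capture_plane_z)
    stop("translocation plane must lie below the capture plane")
  structure(list(capture_plane_z = capture_plane_z,
                 pore_mouth_radius = pore_mouth_radius,
                 translocation_plane_z = translocation_plane_z,
                 evaluation = evaluation),
            class = "classification_config")
}

#' Classify a single frame
#'
#' Boundary convention: an atom exactly on the capture plane counts as
#' above ("below" is a strict inequality), so "all atoms below" is
#' conservative.
#'
#' @param solute_coords n x 3 matrix of solute atom positions, nm.
#' @param config a `classification_config`.
#' @param geometry a `pore_geometry`.
#' @return list with `state` (`"below_all"` / `"above_all"` /
#'   `"straddling"`) and `inside_pore` (all atoms within the mouth radius;
#'   meaningful when below the plane).
#' @export
classify_frame <- function(solute_coords, config, geometry) {
  if (is.null(dim(solute_coords)))
    solute_coords <- matrix(solute_coords, nrow = 1)
  if (nrow(solute_coords) == 0L) stop("empty solute coordinate list")
  ar <- axial_radial_coords(solute_coords, geometry)
  below <- ar[, "axial"] < config$capture_plane_z
  state <- if (all(below)) "below_all"
           else if (!any(below)) "above_all"
           else "straddling"
  list(state = state,
       inside_pore = all(ar[, "radial"] <= config$pore_mouth_radius))
}

#' Classify a trajectory into the capture trichotomy
#'
#' Scans frames in order.  In `latched` mode the first frame with the
#' whole solute below the capture plane and inside the pore sets
#' `label = "captured"` and the latch time; later frames cannot revoke it.
#' If no frame latches, the final frame decides: straddling gives
#' `possible`, fully above gives `failed`.  Frames fully below the plane
#' but *outside* the pore mouth (the solute having drifted down beside the
#' protein) are counted as above for labelling and flagged
#' `excluded_outside_pore` — the automated version of the visual screen
#' for nucleotides below the ring but outside the pore.  `translocated`
#' is set if the whole solute ever drops below the barrel exit plane.
#'
#' @param traj a `trajectory` whose topology flags the solute atoms.
#' @param config a `classification_config`.
#' @param geometry a `pore_geometry`.
#' @return object of class `capture_outcome`: list with `label`,
#'   `latch_time` (ps, `NA` unless captured), `translocated`,
#'   `excluded_outside_pore`.
#' @export
classify_trajectory <- function(traj, config, geometry) {
  stopifnot(inherits(traj, "trajectory"))
  sol <- which(traj$topology$solute)
  if (length(sol) == 0L) stop("trajectory topology has no solute atoms")
  nf <- n_frames(traj)
  if (nf == 0L) stop("empty trajectory")

  # axial/radial for every solute atom in every frame, vectorised
  ax <- sapply(sol, function(i)
    traj$coords[, 3 * i] - geometry$origin[3])
  rx <- sapply(sol, function(i)
    sqrt((traj$coords[, 3 * i - 2] - geometry$origin[1])^2 +
           (traj$coords[, 3 * i - 1] - geometry$origin[2])^2))
  if (is.null(dim(ax))) { ax <- matrix(ax, nrow = nf); rx <- matrix(rx, nrow = nf) }

  below_all <- rowSums(ax < config$capture_plane_z) == length(sol)
  above_all <- rowSums(ax >= config$capture_plane_z) == length(sol)
  inside <- rowSums(rx <= config$pore_mouth_radius) == length(sol)
  capturing <- below_all & inside
  outside_below <- below_all & !inside
  translocated <- any(rowSums(ax < config$translocation_plane_z) ==
                        length(sol))

  finalize <- function(frame) {
    if (outside_below[frame]) "failed"           # below but beside the pore
    else if (below_all[frame]) "captured"
    else if (above_all[frame]) "failed"
    else "possible"
  }

  if (config$evaluation == "latched" && any(capturing)) {
    latch <- which(capturing)[1]
    label <- "captured"
    latch_time <- traj$times[latch]
  } else {
    label <- finalize(nf)
    latch_time <- if (label == "captured")
      traj$times[which(capturing)[1]] else NA_real_
    if (label == "captured" && is.na(latch_time)) {
      # final frame below but never inside-and-below: excluded
      label <- "failed"
    }
  }
  structure(list(label = label, latch_time = latch_time,
                 translocated = translocated,
                 excluded_outside_pore = any(outside_below)),
            class = "capture_outcome")
}

#' Classify every run of a dataset
#'
#' @param manifest condition manifest data.frame with a `trajectory_path`
#'   column.
#' @param dir directory the trajectory paths are relative to.
#' @param topology the shared `topology`.
#' @param config a `classification_config`.
#' @param geometry a `pore_geometry`.
#' @return outcome table: the manifest plus `label`, `latch_time_ps`,
#'   `translocated`, `excluded_outside_pore`.
#' @export
classify_runs <- function(manifest, dir, topology, config, geometry) {
  if (!"trajectory_path" %in% names(manifest))
    stop("manifest has no trajectory_path column")
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    traj <- read_trajectory(topology,
                            file.path(dir, manifest$trajectory_path[i]))
    oc <- classify_trajectory(traj, config, geometry)
    data.frame(label = oc$label, latch_time_ps = oc$latch_time,
               translocated = oc$translocated,
               excluded_outside_pore = oc$excluded_outside_pore)
  })
  cbind(manifest, do.call(rbind, res))
}
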