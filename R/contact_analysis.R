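# Per-residue van der Waals contact analysis: contact frequencies,
# residence events, and the extended / transient / stable classification.
# A residue is in contact in a frame when the minimum heavy-atom distance
# between the solute and that residue is within the cutoff; a residence
# event is a maximal run of consecutive in-contact frames (no gap
# bridging).

#' Contact analysis configuration
#'
#' Thresholds follow the conventions of the capture study: a residue is
#' "extended" when its mean per-run contact fraction over a group of
#' simulations is strictly greater than 5%; a residence event is
#' "transient" when strictly shorter than 100 ps and "stable" when
#' strictly longer than 1 ns.
#'
#' @param cutoff heavy-atom minimum-distance contact threshold, nm (0.4 is
#'   the usual MD contact convention).
#' @param extended_fraction_threshold fraction of frames, in (0, 1).
#' @param transient_max_duration ps; events strictly shorter are transient.
#' @param stable_min_duration ps; events strictly longer are stable.
#' @param averaging `"per_run"` (mean over runs of per-run fractions, the
#'   default reading of "average over all simulations") or `"pooled"`
#'   (fraction over all frames pooled across runs).
#' @param hbond_cutoff donor-acceptor heavy-atom distance for the
#'   hydrogen-bond proxy, nm.
#' @return object of class `contact_config`.
#' @export
contact_config <- function(cutoff = 0.4,
                           extended_fraction_threshold = 0.05,
                           transient_max_duration = 100,
                           stable_min_duration = 1000,
                           averaging = c("per_run", "pooled"),
                           hbond_cutoff = 0.35) {
  averaging <- match.arg(averaging)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (extended_fraction_threshold <= 0 || extended_fraction_threshold >= 1)
    stop("extended_fraction_threshold must be in (0, 1)")
  if (transient_max_duration >= stable_min_duration)
    stop("transient_max_duration must be below stable_min_duration")
  structure(list(cutoff = cutoff,
                 extended_fraction_threshold = extended_fraction_threshold,
                 transient_max_duration = transient_max_duration,
                 stable_min_duration = stable_min_duration,
                 averaging = averaging, hbond_cutoff = hbond_cutoff),
            class = "contact_config")
}

# Protein residue keys and atom grouping for a topology.
.residue_groups <- function(topology) {
  prot <- which(!topology$solute)
  keys <- unique(topology$residue[prot])
  list(prot_idx = prot,
       residues = keys,
       residue_of = match(topology$residue[prot], keys))
}

#' Residues in contact with the solute in one frame
#'
#' @param coords n_atoms x 3 coordinate matrix (nm) for the whole system.
#' @param topology the matching `topology`.
#' @param config a `contact_config`.
#' @return character vector of residue labels within the cutoff.
#' @export
detect_contacts <- function(coords, topology, config = contact_config()) {
  grp <- .residue_groups(topology)
  S <- coords[topology$solute, , drop = FALSE]
  P <- coords[grp$prot_idx, , drop = FALSE]
  d2 <- outer(rowSums(S^2), rowSums(P^2), "+") - 2 * S %*% t(P)
  min_by_atom <- sqrt(pmax(apply(d2, 2, min), 0))
  g <- factor(grp$residue_of, levels = seq_along(grp$residues))
  min_by_res <- vapply(split(min_by_atom, g), min, numeric(1))
  grp$residues[min_by_res <= config$cutoff]
}

# Frames x residues minimum-distance matrix for a whole trajectory
# (compiled kernel; the R brute-force equivalent is kept in the tests).
residue_distance_series <- function(traj, config = contact_config()) {
  grp <- .residue_groups(traj$topology)
  sol <- which(traj$topology$solute)
  d <- residue_min_dist_cpp(traj$coords, sol, grp$prot_idx,
                            grp$residue_of, length(grp$residues))
  colnames(d) <- grp$residues
  d
}

#' Residence events from a per-frame contact series
#'
#' Maximal runs of consecutive in-contact frames; duration = run length x
#' frame interval; gaps are never bridged.
#'
#' @param contact_series logical vector, one entry per frame.
#' @param frame_interval ps between frames.
#' @return data.frame with `start` (ps, time of the first frame of the
#'   run), `end`, `duration` (run length x interval).
#' @export
residence_events <- function(contact_series, frame_interval) {
  if (length(contact_series) == 0L) stop("empty contact series")
  r <- rle(as.logical(contact_series))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  data.frame(start = (starts[on] - 1L) * frame_interval,
             end = (ends[on] - 1L) * frame_interval,
             duration = r$lengths[on] * frame_interval)
}

#' Per-residue contact profile of one trajectory
#'
#' @param traj a `trajectory`.
#' @param config a `contact_config`.
#' @param geometry optional `pore_geometry` for zone annotation.
#' @return object of class `contact_profile`: data.frame with one row per
#'   protein residue (`residue`, `zone`, `contact_fraction`, `n_events`,
#'   `n_transient`, `n_stable`); per-residue event tables are kept in
#'   `attr(, "events")`, the frame interval in `attr(, "frame_interval")`.
#' @export
contact_profile <- function(traj, config = contact_config(),
                            geometry = NULL) {
  d <- residue_distance_series(traj, config)
  inc <- d <= config$cutoff
  interval <- traj$frame_interval
  events <- lapply(colnames(d), function(r)
    residence_events(inc[, r], interval))
  names(events) <- colnames(d)
  prof <- data.frame(
    residue = colnames(d),
    zone = if (is.null(geometry)) NA_character_
           else zone_of(geometry, colnames(d)),
    contact_fraction = colMeans(inc),
    n_events = vapply(events, nrow, integer(1)),
    n_transient = vapply(events, function(e)
      sum(e$duration < config$transient_max_duration), integer(1)),
    n_stable = vapply(events, function(e)
      sum(e$duration > config$stable_min_duration), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(prof) <- c("contact_profile", "data.frame")
  attr(prof, "events") <- events
  attr(prof, "frame_interval") <- interval
  attr(prof, "n_frames") <- nrow(d)
  prof
}

#' Summarise contact profiles by capture outcome
#'
#' Groups runs by outcome label and reports, per residue: the mean contact
#' fraction over the runs in the group (or the pooled-frame fraction,
#' depending on the configured averaging), the extended flag (mean
#' fraction strictly above the threshold), event counts, and the zone.
#'
#' @param profiles named list of `contact_profile`s, keyed by run id.
#' @param outcomes data.frame with `run` and `label` columns covering the
#'   same run ids.
#' @param config a `contact_config`.
#' @return data.frame with one row per (label, residue): `label`,
#'   `residue`, `zone`, `mean_fraction`, `extended`, `n_transient_events`,
#'   `n_stable_events`, `n_runs`.
#' @export
summarize_contacts <- function(profiles, outcomes,
                               config = contact_config()) {
  ids <- names(profiles)
  missing_runs <- setdiff(ids, as.character(outcomes$run))
  if (length(missing_runs))
    stop("no outcome for run(s): ", paste(missing_runs, collapse = ", "))
  labels <- outcomes$label[match(ids, as.character(outcomes$run))]
  out <- lapply(split(seq_along(profiles), labels), function(rows) {
    profs <- profiles[rows]
    res <- profs[[1]]$residue
    frac <- sapply(profs, function(p)
      p$contact_fraction[match(res, p$residue)])
    if (is.null(dim(frac))) frac <- matrix(frac, ncol = length(profs))
    mean_fraction <- if (config$averaging == "per_run") rowMeans(frac)
      else {
        nf <- vapply(profs, function(p) attr(p, "n_frames"), numeric(1))
        as.vector(frac %*% nf / sum(nf))
      }
    data.frame(
      label = labels[rows[1]],
      residue = res,
      zone = profs[[1]]$zone,
      mean_fraction = mean_fraction,
      extended = mean_fraction > config$extended_fraction_threshold,
      n_transient_events = rowSums(vapply(profs, function(p)
        p$n_transient[match(res, p$residue)],
        integer(length(res)), USE.NAMES = FALSE) |>
          matrix(nrow = length(res))),
      n_stable_events = rowSums(vapply(profs, function(p)
        p$n_stable[match(res, p$residue)],
        integer(length(res)), USE.NAMES = FALSE) |>
          matrix(nrow = length(res))),
      n_runs = length(rows),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond proxy contacts
#'
#' Hydrogen bonds are approximated by a donor--acceptor heavy-atom
#' distance criterion without angle terms (coarse models carry no
#' hydrogens): only nitrogen and oxygen atoms on either side are
#' considered, with the tighter `hbond_cutoff`.  Reported separately from
#' van der Waals contacts.
#'
#' @param traj a `trajectory`.
#' @param config a `contact_config`.
#' @return logical matrix, frames x residues: a hydrogen-bond-capable
#'   pair within the cutoff.  Residues with no N/O atoms give `FALSE`
#'   throughout.
#' @export
hbond_series <- function(traj, config = contact_config()) {
  top <- traj$topology
  grp <- .residue_groups(top)
  polar <- top$element %in% c("N", "O")
  sol <- which(top$solute & polar)
  keep <- polar[grp$prot_idx]
  out <- matrix(FALSE, n_frames(traj), length(grp$residues),
                dimnames = list(NULL, grp$residues))
  if (length(sol) == 0L || !any(keep)) return(out)
  d <- residue_min_dist_cpp(traj$coords, sol, grp$prot_idx[keep],
                            match(grp$residue_of[keep],
                                  sort(unique(grp$residue_of[keep]))),
                            length(unique(grp$residue_of[keep])))
  out[, grp$residues[sort(unique(grp$residue_of[keep]))]] <-
    d <= config$hbond_cutoff
  out
}

#' Zone roll-up of extended contacts
#'
#' Fraction of the extended residues in each zone, per outcome group.
#'
#' @param contact_summary output of [summarize_contacts()].
#' @return data.frame with `label`, `zone`, `n_extended`,
#'   `fraction_of_extended`.
#' @export
zone_summary <- function(contact_summary) {
  ext <- contact_summary[contact_summary$extended, ]
  if (nrow(ext) == 0L)
    return(data.frame(label = character(), zone = character(),
                      n_extended = integer(),
                      fraction_of_extended = numeric()))
  out <- do.call(rbind, lapply(split(ext, ext$label), function(g) {
    tab <- table(factor(g$zone, levels = ZONE_LEVELS))
    data.frame(label = g$label[1], zone = names(tab),
               n_extended = as.integer(tab),
               fraction_of_extended = as.numeric(tab) / nrow(g))
  }))
  rownames(out) <- NULL
  out
}
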