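# Topology / trajectory / manifest I/O.
#
# File conventions: PDB files (topology and multi-MODEL coordinate series)
# store angstroms, XYZ files store angstroms with the frame time on the
# comment line ("t= <ps>"); everything in memory is nm and ps.  PDB parsing
# and writing go through bio3d.

DEFAULT_FRAME_INTERVAL <- 10  # ps, assumed when a series carries no times

residue_label <- function(resid, resno) {
  one <- .AA1[resid]
  ifelse(is.na(one), paste0(resid, resno), paste0(one, resno))
}

#' Read a topology from a PDB file
#'
#' Atoms are flagged as solute (the mononucleotide) by residue name: by
#' default any residue that is not one of the 20 standard amino acids.
#'
#' @param path PDB file.
#' @param solute_resid optional character vector of residue names to treat
#'   as solute instead of the default non-amino-acid rule.
#' @return an object of class `topology`: a data.frame with columns
#'   `atom_id`, `atom_name`, `element`, `resid`, `resno`, `chain`,
#'   `residue` (compact label such as `"K8"`), `solute`; reference
#'   coordinates (nm) from the file are kept in `attr(, "ref_coords")`.
#' @export
read_topology <- function(path, solute_resid = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("unparseable PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  ele <- at$elesy
  if (all(is.na(ele))) {
    ele <- tryCatch(suppressWarnings(bio3d::atom2ele(at$elety)),
                    error = function(e) substr(trimws(at$elety), 1, 1))
    # pseudo-atom names used by the surrogate generator
    pseudo <- c(SUG = "C", BAS = "N")
    known <- trimws(at$elety) %in% names(pseudo)
    ele[known] <- pseudo[trimws(at$elety)[known]]
  }
  solute <- if (is.null(solute_resid)) !(at$resid %in% .AA3)
            else at$resid %in% solute_resid
  top <- data.frame(atom_id = at$eleno,
                    atom_name = trimws(at$elety),
                    element = ele,
                    resid = at$resid,
                    resno = at$resno,
                    chain = ifelse(is.na(at$chain), "A", at$chain),
                    residue = residue_label(at$resid, at$resno),
                    solute = solute,
                    stringsAsFactors = FALSE)
  topology(top, ref_coords = angstrom_to_nm(
    matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)))
}

#' Construct a topology object
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `resid`, `resno`, `chain`, `solute` (`residue` is derived if absent).
#' @param ref_coords optional n x 3 reference coordinate matrix, nm.
#' @return object of class `topology`.
#' @export
topology <- function(atoms, ref_coords = NULL) {
  need <- c("atom_id", "atom_name", "element", "resid", "resno", "chain",
            "solute")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("topology missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$atom_id)) stop("duplicate atom_ids in topology")
  if (!any(atoms$solute)) stop("no solute atoms found in topology")
  if (all(atoms$solute)) stop("no protein atoms found in topology")
  if (is.null(atoms$residue))
    atoms$residue <- residue_label(atoms$resid, atoms$resno)
  class(atoms) <- c("topology", "data.frame")
  attr(atoms, "ref_coords") <- ref_coords
  atoms
}

#' Select atoms from a topology
#'
#' Returns row indices in a canonical order (chain, residue number, atom
#' name), so the selection is independent of the file's atom ordering.
#'
#' @param topology a `topology`.
#' @param resno,resid,atom_name,chain optional filters (vectors allowed).
#' @param solute if `TRUE`/`FALSE`, keep only solute / only protein atoms.
#' @return integer vector of row indices into the topology.
#' @export
select_atoms <- function(topology, resno = NULL, resid = NULL,
                         atom_name = NULL, chain = NULL, solute = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(resno)) keep <- keep & topology$resno %in% resno
  if (!is.null(resid)) keep <- keep & topology$resid %in% resid
  if (!is.null(atom_name)) keep <- keep & topology$atom_name %in% atom_name
  if (!is.null(chain)) keep <- keep & topology$chain %in% chain
  if (!is.null(solute)) keep <- keep & topology$solute == solute
  idx <- which(keep)
  idx[order(topology$chain[idx], topology$resno[idx],
            topology$atom_name[idx])]
}

#' Construct a trajectory object
#'
#' @param topology a `topology`.
#' @param coords numeric matrix, frames x (3 * n_atoms), bio3d xyz layout
#'   (x1, y1, z1, x2, ...), nm.
#' @param times frame times in ps, strictly increasing and uniform.
#' @return object of class `trajectory` with fields `topology`, `coords`,
#'   `times`, `frame_interval` (ps).
#' @export
trajectory <- function(topology, coords, times) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L * nrow(topology))
    stop("coordinate columns (", ncol(coords), ") do not match 3 x ",
         nrow(topology), " topology atoms")
  if (length(times) != nrow(coords))
    stop("length(times) must equal the number of frames")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * max(dt))
      stop("frame times must be uniformly spaced")
    interval <- dt[1]
  } else interval <- NA_real_
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), frame_interval = interval),
            class = "trajectory")
}

n_frames <- function(traj) nrow(traj$coords)

# Coordinates of selected atoms in one frame as an n x 3 matrix (nm).
frame_coords <- function(traj, frame, idx = seq_len(nrow(traj$topology))) {
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  matrix(traj$coords[frame, cols], ncol = 3, byrow = TRUE)
}

#' Read a coordinate time series
#'
#' Supports multi-MODEL PDB and XYZ-with-time-comment files.  PDB carries
#' no time axis, so times come from a sidecar CSV (column `time_ps`, one
#' row per frame) or default to a 10 ps interval with a warning.
#'
#' @param topology the matching `topology`.
#' @param path coordinate file (`.pdb` or `.xyz`).
#' @param times_csv optional CSV with a `time_ps` column, one row per frame.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(topology, path, times_csv = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    parsed <- .read_xyz(path, nrow(topology))
    coords <- parsed$coords
    times <- parsed$times
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    coords <- angstrom_to_nm(pdb$xyz)
    if (!is.matrix(coords)) coords <- matrix(coords, nrow = 1)
    if (ncol(coords) != 3L * nrow(topology))
      stop("frame 1: atom count ", ncol(coords) / 3,
           " does not match topology (", nrow(topology), ")")
    times <- NULL
    if (!is.null(times_csv)) {
      tt <- read.csv(times_csv)
      if (!"time_ps" %in% names(tt))
        stop("times CSV lacks a 'time_ps' column: ", times_csv)
      times <- tt$time_ps
      if (length(times) != nrow(coords))
        stop("times CSV has ", length(times), " rows for ",
             nrow(coords), " frames")
    }
    if (is.null(times)) {
      warning("no frame times available; assuming ",
              DEFAULT_FRAME_INTERVAL, " ps interval")
      times <- (seq_len(nrow(coords)) - 1L) * DEFAULT_FRAME_INTERVAL
    }
  }
  trajectory(topology, coords, times)
}

.read_xyz <- function(path, n_atoms_expected) {
  lines <- readLines(path)
  coords <- list()
  times <- numeric()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na))
      stop("frame ", frame, ": bad atom-count line at line ", i)
    if (na != n_atoms_expected)
      stop("frame ", frame, ": atom count ", na,
           " does not match topology (", n_atoms_expected, ")")
    tm <- regmatches(lines[i + 1L],
                     regexpr("t=\\s*[-0-9.eE+]+", lines[i + 1L]))
    times <- c(times, if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) else NA_real_)
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4L))
      stop("frame ", frame, ": malformed atom line")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    coords[[frame]] <- angstrom_to_nm(as.vector(t(xyz)))
    i <- i + 2L + na
  }
  if (frame == 0L) stop("no frames in ", path)
  if (anyNA(times)) {
    warning("no frame times in XYZ comments; assuming ",
            DEFAULT_FRAME_INTERVAL, " ps interval")
    times <- (seq_len(frame) - 1L) * DEFAULT_FRAME_INTERVAL
  }
  list(coords = do.call(rbind, coords), times = times)
}

#' Write a trajectory to disk
#'
#' The format follows the file extension: `.pdb` (multi-MODEL, via bio3d,
#' with a sidecar `<path>.times.csv` for the time axis) or `.xyz` (frame
#' time in the comment line).  Coordinates are written in angstroms at 3
#' decimal places.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  ext <- tolower(tools::file_ext(path))
  top <- traj$topology
  if (ext == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(n_frames(traj))) {
      xyz <- nm_to_angstrom(frame_coords(traj, f))
      writeLines(c(sprintf("%d", nrow(top)),
                   sprintf("t= %.6g", traj$times[f]),
                   sprintf("%-4s %12.3f %12.3f %12.3f", top$atom_name,
                           xyz[, 1], xyz[, 2], xyz[, 3])), con)
    }
  } else {
    bio3d::write.pdb(file = path, xyz = nm_to_angstrom(traj$coords),
                     eleno = top$atom_id, elety = top$atom_name,
                     resid = top$resid, resno = top$resno,
                     chain = top$chain)
    write.csv(data.frame(time_ps = traj$times),
              paste0(path, ".times.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Write a topology (with reference coordinates) to a PDB file
#'
#' @param topology a `topology` carrying `ref_coords`, or supply `coords`.
#' @param path output PDB file.
#' @param coords optional n x 3 coordinate matrix, nm.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path, coords = NULL) {
  if (is.null(coords)) coords <- attr(topology, "ref_coords")
  if (is.null(coords))
    stop("topology carries no reference coordinates; supply coords")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(nm_to_angstrom(coords))),
                   eleno = topology$atom_id, elety = topology$atom_name,
                   resid = topology$resid, resno = topology$resno,
                   chain = topology$chain)
  invisible(path)
}

MANIFEST_COLUMNS <- c("height", "translation", "orientation", "replicate")

#' Read a condition manifest
#'
#' One row per simulation: release height and lateral translation of the
#' nucleotide, phosphate orientation (`up`/`down`) and replicate index,
#' plus optional `trajectory_path`, `seed`, `duration` and `units`
#' (`"nm"`, the default, or `"angstrom"`) columns.  Lengths are converted
#' to nm.
#'
#' @param path CSV file.
#' @return data.frame of conditions (heights/translations in nm).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(m) == 0L) {
    warning("empty manifest: ", path)
    return(m)
  }
  bad <- setdiff(unique(m$orientation), c("up", "down"))
  if (length(bad)) stop("unknown orientation token(s): ",
                        paste(bad, collapse = ", "))
  if ("units" %in% names(m)) {
    if (!all(m$units %in% c("nm", "angstrom")))
      stop("units must be 'nm' or 'angstrom'")
    ang <- m$units == "angstrom"
    m$height[ang] <- angstrom_to_nm(m$height[ang])
    m$translation[ang] <- angstrom_to_nm(m$translation[ang])
    m$units <- NULL
  }
  if (any(m$height < 0) || any(m$translation < 0))
    stop("heights and translations must be non-negative")
  if (any(m$replicate < 1)) stop("replicate indices must be >= 1")
  m
}

#' Write a condition manifest
#'
#' @param conditions data.frame with at least the manifest columns, nm.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(conditions, path) {
  miss <- setdiff(MANIFEST_COLUMNS, names(conditions))
  if (length(miss)) stop("conditions missing column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(conditions, path, row.names = FALSE)
  invisible(path)
}
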