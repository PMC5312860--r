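# Simplified alpha-hemolysin pore geometry: reference residue rings, the
# pore axis, and zone labels for the residues involved in nucleotide capture.

ZONE_LEVELS <- c("vestibule_interior", "vestibule_rim", "cap_surface",
                 "barrel")

# Zone assignment for the residues implicated in capture / possible capture /
# failed capture.  Keys are one-letter-code residue labels (e.g. "K8").
.DEFAULT_ZONE_MAP <- c(
  # interior of the vestibule: extended contacts in captured runs
  D2 = "vestibule_interior", S3 = "vestibule_interior",
  T9 = "vestibule_interior", D13 = "vestibule_interior",
  N293 = "vestibule_interior",
  # edge of the vestibule entrance
  A1 = "vestibule_rim", N6 = "vestibule_rim", K8 = "vestibule_rim",
  G10 = "vestibule_rim", T11 = "vestibule_rim", G15 = "vestibule_rim",
  S16 = "vestibule_rim", I16 = "vestibule_rim", D17 = "vestibule_rim",
  N17 = "vestibule_rim", T18 = "vestibule_rim", T19 = "vestibule_rim",
  V20 = "vestibule_rim",
  # outer surface of the cap: competing binding sites
  D45 = "cap_surface", K46 = "cap_surface", N47 = "cap_surface",
  D47 = "cap_surface")

#' Construct a residue ring
#'
#' A ring is the set of equivalent residues (one per subunit of the
#' heptamer) whose C-alpha positions define a reference plane of the pore:
#' the K8 ring fixes the coordinate origin and the N17 ring fixes the
#' capture plane.
#'
#' @param residue_name three-letter or one-letter residue code.
#' @param residue_number residue sequence number shared by all members.
#' @param positions numeric matrix (members x 3) of C-alpha positions, nm.
#' @return an object of class `residue_ring`.
#' @export
residue_ring <- function(residue_name, residue_number, positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3L)
    stop("a residue ring needs at least 3 members, got ", nrow(positions))
  if (ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix")
  # collinear points cannot define a ring plane
  v1 <- positions[2, ] - positions[1, ]
  v2 <- positions[3, ] - positions[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-12)
    stop("ring positions are collinear (degenerate ring)")
  structure(list(residue_name = residue_name,
                 residue_number = as.integer(residue_number),
                 member_count = nrow(positions),
                 positions = positions),
            class = "residue_ring")
}

#' Centroid of a residue ring
#'
#' Arithmetic mean of the member C-alpha positions.  The K8-ring centroid is
#' the origin of the release-point coordinate system.
#'
#' @param ring a `residue_ring`, or a bare n x 3 coordinate matrix.
#' @return length-3 numeric vector, nm.
#' @export
ring_centroid <- function(ring) {
  pos <- if (inherits(ring, "residue_ring")) ring$positions else as.matrix(ring)
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  if (nrow(pos) == 0L) stop("cannot take the centroid of an empty ring")
  colMeans(pos)
}

# Regular heptagon of C-alpha positions in a horizontal plane.
.heptagon <- function(radius, z, n = 7L, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(radius * cos(ang), radius * sin(ang), rep(z, n))
}

#' Build the default simplified pore geometry
#'
#' A geometric surrogate for the alpha-hemolysin cap/vestibule/barrel
#' architecture.  The K8-ring centroid is the coordinate origin; the pore
#' axis is the z axis, with positive axial coordinates above the vestibule
#' entrance and descent into the pore along -z.  The capture plane is the
#' axial position of the N17 C-alpha ring; the barrel exit plane marks full
#' translocation.
#'
#' Dimensions are alpha-hemolysin-like in proportion but are surrogate
#' values, all configurable.
#'
#' @param pore_mouth_radius radius of the vestibule entrance, nm.
#' @param cap_outer_radius outer radius of the cap surface, nm.
#' @param capture_plane_z axial position of the N17 ring (< 0), nm.
#' @param barrel_exit_z axial position of the barrel exit
#'   (< `capture_plane_z`), nm.
#' @param n17_ring_radius radius of the N17 C-alpha ring, nm.
#' @param zone_map named character vector mapping residue labels ("D45") to
#'   zones; defaults to the built-in assignment.
#' @return an object of class `pore_geometry`.
#' @export
build_default_pore <- function(pore_mouth_radius = 1.3,
                               cap_outer_radius = 5.0,
                               capture_plane_z = -0.5,
                               barrel_exit_z = -10.0,
                               n17_ring_radius = 1.1,
                               zone_map = NULL) {
  if (pore_mouth_radius <= 0)
    stop("pore_mouth_radius must be positive")
  if (pore_mouth_radius >= cap_outer_radius)
    stop("pore_mouth_radius must be smaller than cap_outer_radius")
  if (capture_plane_z >= 0)
    stop("capture_plane_z must lie below the K8 ring (negative axial)")
  if (barrel_exit_z >= capture_plane_z)
    stop("barrel_exit_z must lie below capture_plane_z")
  if (is.null(zone_map)) zone_map <- .DEFAULT_ZONE_MAP
  if (!all(zone_map %in% ZONE_LEVELS))
    stop("unknown zone label in zone_map")

  k8 <- residue_ring("LYS", 8L, .heptagon(pore_mouth_radius, 0))
  n17 <- residue_ring("ASN", 17L,
                      .heptagon(n17_ring_radius, capture_plane_z))
  structure(list(k8_ring = k8,
                 n17_ring = n17,
                 axis = c(0, 0, 1),  # positive axial = above the entrance
                 origin = ring_centroid(k8),
                 capture_plane_z = capture_plane_z,
                 pore_mouth_radius = pore_mouth_radius,
                 cap_outer_radius = cap_outer_radius,
                 barrel_exit_z = barrel_exit_z,
                 zone_map = zone_map),
            class = "pore_geometry")
}

#' Axial/radial coordinates of a point relative to the pore
#'
#' Axial coordinate: signed projection onto the pore axis relative to the
#' K8-ring centroid (positive above the entrance, negative inside the
#' pore).  Radial coordinate: perpendicular distance from the axis.
#'
#' @param point length-3 vector or n x 3 matrix of positions, nm.
#' @param geometry a `pore_geometry`.
#' @return for a single point, named vector `c(axial=, radial=)`; for a
#'   matrix, an n x 2 matrix with columns `axial`, `radial`.
#' @export
axial_radial_coords <- function(point, geometry) {
  stopifnot(inherits(geometry, "pore_geometry"))
  single <- is.null(dim(point))
  p <- if (single) matrix(point, nrow = 1) else as.matrix(point)
  rel <- sweep(p, 2, geometry$origin)
  axial <- drop(rel %*% geometry$axis)
  perp <- rel - outer(axial, geometry$axis)
  radial <- sqrt(rowSums(perp^2))
  if (single) c(axial = axial, radial = radial)
  else cbind(axial = axial, radial = radial)
}

#' Zone label of a residue
#'
#' @param geometry a `pore_geometry`.
#' @param residue residue label(s) in one-letter-code form, e.g. `"D45"`.
#' @return character vector of zone labels (`NA` for unzoned residues).
#' @export
zone_of <- function(geometry, residue) {
  stopifnot(inherits(geometry, "pore_geometry"))
  unname(geometry$zone_map[residue])
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat("Simplified nanopore geometry\n")
  cat(sprintf("  pore mouth radius : %.2f nm\n", x$pore_mouth_radius))
  cat(sprintf("  cap outer radius  : %.2f nm\n", x$cap_outer_radius))
  cat(sprintf("  capture plane (N17 ring): %.2f nm\n", x$capture_plane_z))
  cat(sprintf("  barrel exit plane : %.2f nm\n", x$barrel_exit_z))
  cat(sprintf("  zoned residues    : %d\n", length(x$zone_map)))
  invisible(x)
}
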