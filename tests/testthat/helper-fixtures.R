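# Shared fixtures, built in code.

fixture_geometry <- function() build_default_pore()

# Minimal system: the K8 C-alpha ring plus the 3-pseudo-atom solute.
# Cheap enough for property loops that do not need the full heptamer.
fixture_small_topology <- function(geometry = fixture_geometry()) {
  ring <- geometry$k8_ring$positions
  atoms <- data.frame(
    atom_id = 1:10,
    atom_name = c(rep("CA", 7), "P", "SUG", "BAS"),
    element = c(rep("C", 7), "P", "C", "N"),
    resid = c(rep("LYS", 7), rep("CMP", 3)),
    resno = c(rep(8L, 7), rep(1L, 3)),
    chain = c(LETTERS[1:7], rep("X", 3)),
    solute = c(rep(FALSE, 7), rep(TRUE, 3)))
  topology(atoms, ref_coords = rbind(ring, matrix(0, 3, 3)))
}

# A hand-built trajectory from solute centre positions (n x 3, nm):
# the solute pseudo-atoms sit at centre + (0, 0, +/-0.25).
fixture_trajectory <- function(centres, topology = fixture_small_topology(),
                               interval = 10) {
  centres <- as.matrix(centres)
  nf <- nrow(centres)
  ref <- attr(topology, "ref_coords")
  coords <- matrix(rep(as.vector(t(ref)), each = nf), nrow = nf)
  off <- c(P = 0.25, SUG = 0, BAS = -0.25)
  for (i in which(topology$solute)) {
    coords[, 3 * i - 2] <- centres[, 1]
    coords[, 3 * i - 1] <- centres[, 2]
    coords[, 3 * i] <- centres[, 3] + off[[topology$atom_name[i]]]
  }
  trajectory(topology, coords, times = (seq_len(nf) - 1) * interval)
}

# Minimal PDB text fixture: 7 K8 CA atoms + one CMP phosphate.
write_fixture_pdb <- function(path) {
  ring <- porecap::build_default_pore()$k8_ring$positions * 10  # angstrom
  lines <- c(
    sprintf("ATOM  %5d  CA  LYS %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            1:7, LETTERS[1:7], 8, ring[, 1], ring[, 2], ring[, 3]),
    sprintf("HETATM%5d  P   CMP X%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            8, 1, 0, 0, 30),
    "END")
  writeLines(lines, path)
  path
}
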