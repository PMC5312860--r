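#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin descent of a rigid 3-pseudo-atom solute towards a
// funnel pore.  Geometry: membrane/cap surface at z = 0 (everywhere except
// the pore mouth, radius mouth_radius about the z axis), capture plane at
// capture_plane_z < 0, barrel running down to barrel_exit_z.  The solute is
// a point centre with rigid axial extent [zoff_lo, zoff_hi] (nm).  Distances
// in nm, time in ps, drift in nm/ns, diffusion in nm^2/ns.
//
// Rules, in step order:
//  - sticky pause: while uncaptured, resting on the cap annulus (mouth <
//    r <= cap_outer, lowest atom within 0.05 nm of the surface) the move is
//    skipped with probability sticky_affinity (surface binding surrogate);
//  - proposal: constant downward drift plus isotropic Gaussian noise;
//  - membrane reflection: a proposal putting the lowest atom below z = 0
//    while the centre was above the surface and lands at r > mouth_radius
//    is reflected in the surface plane;
//  - pore wall: once below the surface, radial excursions beyond
//    mouth_radius reflect off the wall;
//  - capture (absorbing): first step with the highest atom below
//    capture_plane_z at r <= mouth_radius latches; afterwards the solute is
//    confined below the plane (reflection from below).
//
// Uses R's RNG so results are reproducible from set.seed().
// [[Rcpp::export]]
List langevin_path_cpp(NumericVector start, double drift, double diffusion,
                       double dt_ps, int n_steps, int frame_stride,
                       double capture_plane_z, double mouth_radius,
                       double cap_outer_radius, double barrel_exit_z,
                       double sticky_affinity,
                       double zoff_lo, double zoff_hi) {
  if (frame_stride < 1) stop("frame_stride must be >= 1");
  const double dt_ns = dt_ps / 1000.0;
  const double sd = std::sqrt(2.0 * diffusion * dt_ns);
  const double step_drift = drift * dt_ns;

  double x = start[0], y = start[1], z = start[2];
  bool captured = false, translocated = false;
  int latch_step = NA_INTEGER;

  const int n_frames = n_steps / frame_stride + 1;
  NumericMatrix frames(n_frames, 3);
  frames(0, 0) = x; frames(0, 1) = y; frames(0, 2) = z;
  int fi = 1;

  for (int s = 1; s <= n_steps; ++s) {
    const double r = std::sqrt(x * x + y * y);

    bool paused = false;
    if (!captured && sticky_affinity > 0.0 && r > mouth_radius &&
        r <= cap_outer_radius && (z + zoff_lo) <= 0.05) {
      if (unif_rand() < sticky_affinity) paused = true;
    }

    if (!paused) {
      double nx = x + sd * norm_rand();
      double ny = y + sd * norm_rand();
      double nz = z + sd * norm_rand() - step_drift;
      double nr = std::sqrt(nx * nx + ny * ny);

      if ((nz + zoff_lo) < 0.0 && nr > mouth_radius) {
        if ((z + zoff_lo) >= 0.0) {
          // came from above: bounce off the membrane/cap surface
          nz = 2.0 * (-zoff_lo) - nz;
        } else {
          // inside the pore: bounce off the cylindrical wall
          double tr = 2.0 * mouth_radius - nr;
          if (tr < 0.0) tr = 0.999 * mouth_radius;
          if (nr > 0.0) { nx *= tr / nr; ny *= tr / nr; }
          nr = std::sqrt(nx * nx + ny * ny);
        }
      }

      if (!captured && (nz + zoff_hi) < capture_plane_z &&
          nr <= mouth_radius) {
        captured = true;
        latch_step = s;
      }

      if (captured) {
        if ((nz + zoff_hi) > capture_plane_z)  // no exit once captured
          nz = 2.0 * (capture_plane_z - zoff_hi) - nz;
        nr = std::sqrt(nx * nx + ny * ny);
        if (nr > mouth_radius) {
          double tr = 2.0 * mouth_radius - nr;
          if (tr < 0.0) tr = 0.999 * mouth_radius;
          if (nr > 0.0) { nx *= tr / nr; ny *= tr / nr; }
        }
      }

      x = nx; y = ny; z = nz;
    }

    if ((z + zoff_hi) < barrel_exit_z) translocated = true;

    if (s % frame_stride == 0) {
      frames(fi, 0) = x; frames(fi, 1) = y; frames(fi, 2) = z;
      ++fi;
    }
  }

  return List::create(_["frames"] = frames,
                      _["captured"] = captured,
                      _["latch_step"] = latch_step,
                      _["translocated"] = translocated);
}

// Per-frame minimum heavy-atom distance between the solute and each protein
// residue.  coords is n_frames x (3 * n_atoms) (bio3d xyz layout, nm);
// residue_of maps each protein atom (1-based into prot_idx) to a residue
// group 1..n_res.
// [[Rcpp::export]]
NumericMatrix residue_min_dist_cpp(NumericMatrix coords,
                                   IntegerVector solute_idx,
                                   IntegerVector prot_idx,
                                   IntegerVector residue_of,
                                   int n_res) {
  const int nf = coords.nrow();
  const int ns = solute_idx.size();
  const int np = prot_idx.size();
  if (residue_of.size() != np) stop("residue_of must match prot_idx");
  NumericMatrix out(nf, n_res);
  std::fill(out.begin(), out.end(), R_PosInf);

  for (int f = 0; f < nf; ++f) {
    for (int p = 0; p < np; ++p) {
      const int pa = prot_idx[p] - 1;
      const double px = coords(f, 3 * pa), py = coords(f, 3 * pa + 1),
                   pz = coords(f, 3 * pa + 2);
      const int g = residue_of[p] - 1;
      double best = out(f, g);
      for (int a = 0; a < ns; ++a) {
        const int sa = solute_idx[a] - 1;
        const double dx = coords(f, 3 * sa) - px;
        const double dy = coords(f, 3 * sa + 1) - py;
        const double dz = coords(f, 3 * sa + 2) - pz;
        const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < best) best = d;
      }
      out(f, g) = best;
    }
  }
  return out;
}
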