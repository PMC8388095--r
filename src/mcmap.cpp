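// Screened-Coulomb grid evaluation, trilinear interpolation, and the
// rigid-body Metropolis Monte Carlo engine. All geometry in Angstrom,
// potentials in kBT/e, energies in kBT, charges in elementary charge.
//
// Grid storage is R column-major: value(ix,iy,iz) at linear index
// ix + nx*(iy + ny*iz), 0-based.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 stream with Box-Muller normals. Self-contained so that
// ensembles are bit-reproducible across platforms and per-run streams can be
// derived independently from one master seed (runs are order-independent).
// ---------------------------------------------------------------------------

struct MapRng {
  uint64_t state;
  bool have_spare;
  double spare;
  explicit MapRng(uint64_t seed) : state(seed), have_spare(false), spare(0.0) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1); never exactly 0 so log() below is safe
  double unif() {
    return (static_cast<double>(next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

static uint64_t mix_run_seed(uint64_t master, uint64_t run) {
  // one splitmix64 scramble of (master, run) so streams are decorrelated
  uint64_t z = master + 0x9E3779B97F4A7C15ULL * (run + 1);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// ---------------------------------------------------------------------------
// Quaternions: q = (w, x, y, z), unit norm, acting as v' = q v q*
// ---------------------------------------------------------------------------

static inline void quat_rotate(const double q[4], const double v[3], double out[3]) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  // t = 2 q_vec x v
  double tx = 2.0 * (y * v[2] - z * v[1]);
  double ty = 2.0 * (z * v[0] - x * v[2]);
  double tz = 2.0 * (x * v[1] - y * v[0]);
  out[0] = v[0] + w * tx + (y * tz - z * ty);
  out[1] = v[1] + w * ty + (z * tx - x * tz);
  out[2] = v[2] + w * tz + (x * ty - y * tx);
}

static inline void quat_mul(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

static inline void quat_normalize(double q[4]) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= n;
}

// [[Rcpp::export]]
NumericMatrix cpp_quat_rotate(NumericVector q, NumericMatrix pts) {
  double qq[4] = { q[0], q[1], q[2], q[3] };
  NumericMatrix out(pts.nrow(), 3);
  for (int i = 0; i < pts.nrow(); ++i) {
    double v[3] = { pts(i,0), pts(i,1), pts(i,2) }, r[3];
    quat_rotate(qq, v, r);
    out(i,0) = r[0]; out(i,1) = r[1]; out(i,2) = r[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Screened-Coulomb potential: phi(x) = lB * sum_i q_i exp(-kappa r_i) / r_i
// with lB the Bjerrum length (Ang) at the stated temperature/dielectric,
// giving phi in kBT/e. r is clamped below at r_min; clamped evaluations are
// counted so callers can flag near-singular grid nodes.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_potential_points(NumericMatrix coords, NumericVector charges,
                          NumericMatrix points, double kappa, double bjerrum,
                          double r_min) {
  const int na = coords.nrow(), np = points.nrow();
  NumericVector phi(np);
  int n_clamped = 0;
  for (int p = 0; p < np; ++p) {
    double acc = 0.0;
    const double px = points(p,0), py = points(p,1), pz = points(p,2);
    bool clamped = false;
    for (int i = 0; i < na; ++i) {
      double dx = px - coords(i,0), dy = py - coords(i,1), dz = pz - coords(i,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < r_min) { r = r_min; clamped = true; }
      acc += charges[i] * std::exp(-kappa * r) / r;
    }
    if (clamped) ++n_clamped;
    phi[p] = bjerrum * acc;
  }
  return List::create(_["phi"] = phi, _["n_clamped"] = n_clamped);
}

// [[Rcpp::export]]
List cpp_potential_grid(NumericMatrix coords, NumericVector charges,
                        NumericVector origin, double spacing, IntegerVector dims,
                        double kappa, double bjerrum, double r_min) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = coords.nrow();
  NumericVector phi(static_cast<R_xlen_t>(nx) * ny * nz);
  int n_clamped = 0;
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double z = origin[2] + iz * spacing;
    for (int iy = 0; iy < ny; ++iy) {
      const double y = origin[1] + iy * spacing;
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double x = origin[0] + ix * spacing;
        double acc = 0.0;
        bool clamped = false;
        for (int i = 0; i < na; ++i) {
          double dx = x - coords(i,0), dy = y - coords(i,1), dz = z - coords(i,2);
          double r = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (r < r_min) { r = r_min; clamped = true; }
          acc += charges[i] * std::exp(-kappa * r) / r;
        }
        if (clamped) ++n_clamped;
        phi[idx] = bjerrum * acc;
      }
    }
  }
  return List::create(_["phi"] = phi, _["n_clamped"] = n_clamped);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation. outside = 0: throw, outside = 1: return 0 (far
// field). Points exactly on the upper face are treated as inside.
// ---------------------------------------------------------------------------

static inline double trilinear_one(const double* v, const double* origin,
                                   double spacing, const int* n,
                                   double x, double y, double z,
                                   int outside, bool* was_outside) {
  double u[3] = { (x - origin[0]) / spacing,
                  (y - origin[1]) / spacing,
                  (z - origin[2]) / spacing };
  int i0[3];
  double f[3];
  for (int k = 0; k < 3; ++k) {
    if (u[k] < 0.0 || u[k] > n[k] - 1.0) {
      if (outside == 0) stop("interpolation point outside grid");
      *was_outside = true;
      return 0.0;
    }
    i0[k] = static_cast<int>(std::floor(u[k]));
    if (i0[k] > n[k] - 2) i0[k] = n[k] - 2;  // upper-face queries
    f[k] = u[k] - i0[k];
  }
  const int nx = n[0], ny = n[1];
  #define V(ix,iy,iz) v[(ix) + nx * ((iy) + static_cast<R_xlen_t>(ny) * (iz))]
  double c00 = V(i0[0],   i0[1],   i0[2]) * (1-f[0]) + V(i0[0]+1, i0[1],   i0[2]) * f[0];
  double c10 = V(i0[0],   i0[1]+1, i0[2]) * (1-f[0]) + V(i0[0]+1, i0[1]+1, i0[2]) * f[0];
  double c01 = V(i0[0],   i0[1],   i0[2]+1) * (1-f[0]) + V(i0[0]+1, i0[1],   i0[2]+1) * f[0];
  double c11 = V(i0[0],   i0[1]+1, i0[2]+1) * (1-f[0]) + V(i0[0]+1, i0[1]+1, i0[2]+1) * f[0];
  #undef V
  double c0 = c00 * (1-f[1]) + c10 * f[1];
  double c1 = c01 * (1-f[1]) + c11 * f[1];
  return c0 * (1-f[2]) + c1 * f[2];
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, NumericVector origin,
                            double spacing, IntegerVector dims,
                            NumericMatrix points, int outside) {
  int n[3] = { dims[0], dims[1], dims[2] };
  double o[3] = { origin[0], origin[1], origin[2] };
  NumericVector out(points.nrow());
  bool dummy = false;
  for (int p = 0; p < points.nrow(); ++p)
    out[p] = trilinear_one(REAL(values), o, spacing, n,
                           points(p,0), points(p,1), points(p,2), outside, &dummy);
  return out;
}

// ---------------------------------------------------------------------------
// Cell list over receptor atoms for hard-core clash tests.
// Clash rule: any ligand/receptor pair with d < overlap * (r_i + r_j).
// ---------------------------------------------------------------------------

struct CellList {
  double cell;            // cell edge, >= overlap * (max ri + max rj)
  double lo[3];
  int n[3];
  std::vector<std::vector<int> > cells;
  const NumericMatrix* coords;
  const NumericVector* radii;

  void build(const NumericMatrix& xyz, const NumericVector& rad, double cell_edge) {
    coords = &xyz; radii = &rad; cell = cell_edge;
    double hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i = 0; i < xyz.nrow(); ++i)
      for (int k = 0; k < 3; ++k) {
        if (xyz(i,k) < lo[k]) lo[k] = xyz(i,k);
        if (xyz(i,k) > hi[k]) hi[k] = xyz(i,k);
      }
    for (int k = 0; k < 3; ++k) {
      lo[k] -= 1e-9;
      n[k] = std::max(1, static_cast<int>(std::floor((hi[k] - lo[k]) / cell)) + 1);
    }
    cells.assign(static_cast<size_t>(n[0]) * n[1] * n[2], std::vector<int>());
    for (int i = 0; i < xyz.nrow(); ++i) {
      int c[3];
      for (int k = 0; k < 3; ++k)
        c[k] = std::min(n[k] - 1, static_cast<int>((xyz(i,k) - lo[k]) / cell));
      cells[c[0] + n[0] * (c[1] + static_cast<size_t>(n[1]) * c[2])].push_back(i);
    }
  }

  // true if an atom at p with radius rp clashes with any receptor atom
  bool clash_atom(const double p[3], double rp, double overlap) const {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double u = (p[k] - lo[k]) / cell;
      c[k] = static_cast<int>(std::floor(u));
    }
    for (int dz = -1; dz <= 1; ++dz) {
      int iz = c[2] + dz; if (iz < 0 || iz >= n[2]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = c[1] + dy; if (iy < 0 || iy >= n[1]) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = c[0] + dx; if (ix < 0 || ix >= n[0]) continue;
          const std::vector<int>& cc =
            cells[ix + n[0] * (iy + static_cast<size_t>(n[1]) * iz)];
          for (size_t m = 0; m < cc.size(); ++m) {
            int i = cc[m];
            double ddx = p[0] - (*coords)(i,0);
            double ddy = p[1] - (*coords)(i,1);
            double ddz = p[2] - (*coords)(i,2);
            double cut = overlap * (rp + (*radii)[i]);
            if (ddx*ddx + ddy*ddy + ddz*ddz < cut * cut) return true;
          }
        }
      }
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// Pose energy: E [kBT] = sum_j q_j phi(R x_j + t); +Inf on hard-core clash.
// Ligand coordinates are body-frame with the centre of mass at the origin.
// ---------------------------------------------------------------------------

struct MapSystem {
  const double* grid;
  double origin[3];
  double spacing;
  int dims[3];
  CellList cl;
  double rec_com[3];
  double rec_bound;       // receptor bounding radius + max pair cut, from COM
  double lig_bound;       // ligand bounding radius (body frame)
  double overlap;
  bool has_receptor;
};

static double pose_energy(const MapSystem& sys, const NumericMatrix& lig,
                          const NumericVector& q, const NumericVector& lr,
                          const double t[3], const double quat[4]) {
  const int nl = lig.nrow();
  // bounding-sphere pre-check: clash possible only if spheres overlap
  bool near = false;
  if (sys.has_receptor) {
    double dx = t[0] - sys.rec_com[0], dy = t[1] - sys.rec_com[1],
           dz = t[2] - sys.rec_com[2];
    near = dx*dx + dy*dy + dz*dz <
      (sys.rec_bound + sys.lig_bound) * (sys.rec_bound + sys.lig_bound);
  }
  double e = 0.0;
  bool dummy = false;
  for (int j = 0; j < nl; ++j) {
    double v[3] = { lig(j,0), lig(j,1), lig(j,2) }, p[3];
    quat_rotate(quat, v, p);
    p[0] += t[0]; p[1] += t[1]; p[2] += t[2];
    if (near && sys.cl.clash_atom(p, lr[j], sys.overlap))
      return R_PosInf;
    if (q[j] != 0.0)
      e += q[j] * trilinear_one(sys.grid, sys.origin, sys.spacing, sys.dims,
                                p[0], p[1], p[2], 1, &dummy);
  }
  return e;
}

static void build_system(MapSystem& sys,
                         const NumericVector& grid_values, const NumericVector& origin,
                         double spacing, const IntegerVector& dims,
                         const NumericMatrix& rec_coords, const NumericVector& rec_radii,
                         const NumericVector& rec_com, const NumericMatrix& lig_coords,
                         const NumericVector& lig_radii, double overlap) {
  sys.grid = REAL(grid_values);
  for (int k = 0; k < 3; ++k) {
    sys.origin[k] = origin[k];
    sys.dims[k] = dims[k];
    sys.rec_com[k] = rec_com[k];
  }
  sys.spacing = spacing;
  sys.overlap = overlap;
  sys.has_receptor = rec_coords.nrow() > 0;
  double rmax_rec = 0.0, rmax_lig = 0.0;
  for (int i = 0; i < rec_radii.size(); ++i)
    if (rec_radii[i] > rmax_rec) rmax_rec = rec_radii[i];
  for (int j = 0; j < lig_radii.size(); ++j)
    if (lig_radii[j] > rmax_lig) rmax_lig = lig_radii[j];
  double pair_cut = overlap * (rmax_rec + rmax_lig);
  if (sys.has_receptor)
    sys.cl.build(rec_coords, rec_radii, std::max(pair_cut, 1.0));
  double rb = 0.0;
  for (int i = 0; i < rec_coords.nrow(); ++i) {
    double dx = rec_coords(i,0) - rec_com[0], dy = rec_coords(i,1) - rec_com[1],
           dz = rec_coords(i,2) - rec_com[2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (d > rb) rb = d;
  }
  sys.rec_bound = rb + pair_cut;
  double lb = 0.0;
  for (int j = 0; j < lig_coords.nrow(); ++j) {
    double d = std::sqrt(lig_coords(j,0)*lig_coords(j,0) +
                         lig_coords(j,1)*lig_coords(j,1) +
                         lig_coords(j,2)*lig_coords(j,2));
    if (d > lb) lb = d;
  }
  sys.lig_bound = lb;
}

// [[Rcpp::export]]
double cpp_pose_energy(NumericMatrix lig_coords, NumericVector lig_charges,
                       NumericVector lig_radii, NumericVector translation,
                       NumericVector quaternion, NumericVector grid_values,
                       NumericVector origin, double spacing, IntegerVector dims,
                       NumericMatrix rec_coords, NumericVector rec_radii,
                       NumericVector rec_com, double overlap) {
  MapSystem sys;
  build_system(sys, grid_values, origin, spacing, dims, rec_coords, rec_radii,
               rec_com, lig_coords, lig_radii, overlap);
  double t[3] = { translation[0], translation[1], translation[2] };
  double q[4] = { quaternion[0], quaternion[1], quaternion[2], quaternion[3] };
  return pose_energy(sys, lig_coords, lig_charges, lig_radii, t, q);
}

// ---------------------------------------------------------------------------
// The Metropolis engine. Each run: start from a uniformly random non-clashing
// pose within the d_max ball, propose Gaussian translations and small-angle
// rotations, reject beyond d_max, accept with min(1, exp(-dE)). Poses are
// recorded every record_every steps after burn_in.
// ---------------------------------------------------------------------------

static void random_unit_quat(MapRng& rng, double q[4]) {
  for (int k = 0; k < 4; ++k) q[k] = rng.norm();
  quat_normalize(q);
}

// [[Rcpp::export]]
List cpp_run_mapping(NumericMatrix rec_coords, NumericVector rec_radii,
                     NumericVector rec_com, NumericMatrix lig_coords,
                     NumericVector lig_charges, NumericVector lig_radii,
                     NumericVector grid_values, NumericVector origin,
                     double spacing, IntegerVector dims,
                     int n_runs, int n_steps, int burn_in, int record_every,
                     double translation_step, double rotation_step,
                     double d_max, double overlap, double master_seed,
                     int max_start_retries) {
  MapSystem sys;
  build_system(sys, grid_values, origin, spacing, dims, rec_coords, rec_radii,
               rec_com, lig_coords, lig_radii, overlap);
  const int per_run = (n_steps - burn_in) / record_every;
  if (per_run <= 0) stop("no poses would be recorded: n_steps - burn_in < record_every");
  NumericMatrix out(static_cast<R_xlen_t>(n_runs) * per_run, 8);
  IntegerVector run_id(static_cast<R_xlen_t>(n_runs) * per_run);
  NumericVector acc_rate(n_runs);
  const uint64_t mseed = static_cast<uint64_t>(master_seed);

  R_xlen_t row = 0;
  for (int run = 0; run < n_runs; ++run) {
    MapRng rng(mix_run_seed(mseed, static_cast<uint64_t>(run)));
    double t[3], q[4];
    double e = R_PosInf;
    int tries = 0;
    while (!std::isfinite(e)) {
      if (++tries > max_start_retries)
        stop("could not find a clash-free start pose (run %d)", run + 1);
      // uniform in the d_max ball: direction from normals, radius ~ U^(1/3)
      double dir[3] = { rng.norm(), rng.norm(), rng.norm() };
      double nn = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
      double r = d_max * std::cbrt(rng.unif());
      for (int k = 0; k < 3; ++k) t[k] = rec_com[k] + r * dir[k] / nn;
      random_unit_quat(rng, q);
      e = pose_energy(sys, lig_coords, lig_charges, lig_radii, t, q);
    }
    long accepted = 0;
    for (int step = 1; step <= n_steps; ++step) {
      double tp[3], qp[4], dq[4];
      for (int k = 0; k < 3; ++k) tp[k] = t[k] + translation_step * rng.norm();
      double ax[3] = { rng.norm(), rng.norm(), rng.norm() };
      double an = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
      double angle = rotation_step * rng.norm();
      double s = std::sin(0.5 * angle) / an;
      dq[0] = std::cos(0.5 * angle);
      dq[1] = s * ax[0]; dq[2] = s * ax[1]; dq[3] = s * ax[2];
      quat_mul(dq, q, qp);
      quat_normalize(qp);
      double dx = tp[0] - rec_com[0], dy = tp[1] - rec_com[1], dz = tp[2] - rec_com[2];
      bool ok = dx*dx + dy*dy + dz*dz <= d_max * d_max;
      if (ok) {
        double ep = pose_energy(sys, lig_coords, lig_charges, lig_radii, tp, qp);
        double de = ep - e;
        if (de <= 0.0 || rng.unif() < std::exp(-de)) {
          t[0] = tp[0]; t[1] = tp[1]; t[2] = tp[2];
          q[0] = qp[0]; q[1] = qp[1]; q[2] = qp[2]; q[3] = qp[3];
          e = ep;
          ++accepted;
        }
      }
      if (step > burn_in && (step - burn_in) % record_every == 0) {
        out(row, 0) = t[0]; out(row, 1) = t[1]; out(row, 2) = t[2];
        out(row, 3) = q[0]; out(row, 4) = q[1]; out(row, 5) = q[2]; out(row, 6) = q[3];
        out(row, 7) = e;
        run_id[row] = run + 1;
        ++row;
      }
    }
    acc_rate[run] = static_cast<double>(accepted) / n_steps;
  }
  return List::create(_["poses"] = out, _["run"] = run_id,
                      _["acceptance"] = acc_rate);
}

// ---------------------------------------------------------------------------
// Contact statistics: for each receptor atom group (residue or cofactor),
// the number of poses with any group atom within cutoff of any transformed
// ligand atom, and the minimal pair distance seen over all poses.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_contact_stats(NumericMatrix rec_coords, IntegerVector group,
                       int n_groups, NumericMatrix lig_coords,
                       NumericMatrix poses, double cutoff) {
  const int nr = rec_coords.nrow(), nl = lig_coords.nrow(), np = poses.nrow();
  IntegerVector counts(n_groups);
  NumericVector min_dist(n_groups, R_PosInf);
  std::vector<char> hit(n_groups);
  std::vector<double> lig_t(static_cast<size_t>(nl) * 3);
  for (int p = 0; p < np; ++p) {
    double t[3] = { poses(p,0), poses(p,1), poses(p,2) };
    double q[4] = { poses(p,3), poses(p,4), poses(p,5), poses(p,6) };
    for (int j = 0; j < nl; ++j) {
      double v[3] = { lig_coords(j,0), lig_coords(j,1), lig_coords(j,2) }, r[3];
      quat_rotate(q, v, r);
      lig_t[3*j]   = r[0] + t[0];
      lig_t[3*j+1] = r[1] + t[1];
      lig_t[3*j+2] = r[2] + t[2];
    }
    std::fill(hit.begin(), hit.end(), 0);
    for (int i = 0; i < nr; ++i) {
      const int g = group[i];
      for (int j = 0; j < nl; ++j) {
        double dx = rec_coords(i,0) - lig_t[3*j];
        double dy = rec_coords(i,1) - lig_t[3*j+1];
        double dz = rec_coords(i,2) - lig_t[3*j+2];
        double d2 = dx*dx + dy*dy + dz*dz;
        double d = std::sqrt(d2);
        if (d < min_dist[g]) min_dist[g] = d;
        if (d < cutoff) hit[g] = 1;
      }
    }
    for (int g = 0; g < n_groups; ++g)
      if (hit[g]) ++counts[g];
  }
  return List::create(_["count"] = counts, _["min_dist"] = min_dist);
}
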