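#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// -------------------------------------------------------------------------
// Production local 3D gamma.
//
// The search lattice is axis-aligned in mm with step `step`, clipped to the
// sphere of radius `radius` around each reference voxel. Because reference
// voxels sit on the grid, the trilinear weights of a lattice offset are the
// same for every reference voxel: the integer base shift and the 8 corner
// weights are precomputed per offset, offsets are sorted by distance, and
// the per-voxel scan stops once the pure distance term of the next offset
// exceeds the running minimum (an exact lower-bound termination rule).
// -------------------------------------------------------------------------

struct Offset {
  double dist2;        // squared Euclidean length in mm^2
  int di, dj, dk;      // integer base shift in voxels
  double w[8];         // trilinear corner weights
  int ui, uj, uk;      // upper-corner shifts (base or base+1 per axis)
};

static void axis_split(double f, int &base, int &upper, double &whi) {
  double fb = std::floor(f);
  base = (int)fb;
  whi = f - fb;
  if (whi < 1e-12) { upper = base; whi = 0.0; }        // exact lattice hit
  else upper = base + 1;
}

static std::vector<Offset> build_offsets(double step, double radius,
                                         const double *spacing) {
  std::vector<Offset> offs;
  int nmax = (int)std::floor(radius / step + 1e-9);
  double r2 = radius * radius;
  for (int a = -nmax; a <= nmax; ++a)
    for (int b = -nmax; b <= nmax; ++b)
      for (int c = -nmax; c <= nmax; ++c) {
        double ox = a * step, oy = b * step, oz = c * step;
        double d2 = ox * ox + oy * oy + oz * oz;
        if (d2 > r2 + 1e-9) continue;
        Offset o;
        o.dist2 = d2;
        double w1, w2, w3;
        axis_split(ox / spacing[0], o.di, o.ui, w1);
        axis_split(oy / spacing[1], o.dj, o.uj, w2);
        axis_split(oz / spacing[2], o.dk, o.uk, w3);
        o.w[0] = (1 - w1) * (1 - w2) * (1 - w3);
        o.w[1] = w1 * (1 - w2) * (1 - w3);
        o.w[2] = (1 - w1) * w2 * (1 - w3);
        o.w[3] = w1 * w2 * (1 - w3);
        o.w[4] = (1 - w1) * (1 - w2) * w3;
        o.w[5] = w1 * (1 - w2) * w3;
        o.w[6] = (1 - w1) * w2 * w3;
        o.w[7] = w1 * w2 * w3;
        offs.push_back(o);
      }
  return offs;
}

// Trilinear sample of `ev` at reference voxel (i,j,k) displaced by `o`.
// False when a needed corner falls outside the grid.
static inline bool sample(const double *ev, int n1, int n2, int n3,
                          int i, int j, int k, const Offset &o, double &out) {
  int i0 = i + o.di, i1 = i + o.ui;
  int j0 = j + o.dj, j1 = j + o.uj;
  int k0 = k + o.dk, k1 = k + o.uk;
  if (i0 < 0 || i1 > n1 - 1 || j0 < 0 || j1 > n2 - 1 || k0 < 0 || k1 > n3 - 1)
    return false;
  long s0 = (long)n1, s1 = (long)n1 * n2;
  out = o.w[0] * ev[i0 + s0 * j0 + s1 * k0] + o.w[1] * ev[i1 + s0 * j0 + s1 * k0] +
        o.w[2] * ev[i0 + s0 * j1 + s1 * k0] + o.w[3] * ev[i1 + s0 * j1 + s1 * k0] +
        o.w[4] * ev[i0 + s0 * j0 + s1 * k1] + o.w[5] * ev[i1 + s0 * j0 + s1 * k1] +
        o.w[6] * ev[i0 + s0 * j1 + s1 * k1] + o.w[7] * ev[i1 + s0 * j1 + s1 * k1];
  return true;
}

// [[Rcpp::export(name = ".gamma_search_cpp")]]
NumericVector gamma_search_cpp(NumericVector reference, NumericVector evaluated,
                               IntegerVector dims, NumericVector spacing,
                               double dose_tol_pct, double dta,
                               double exclusion_fraction, double step,
                               double radius, bool global_norm) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *ref = reference.begin();
  const double *ev = evaluated.begin();
  double sp[3] = {spacing[0], spacing[1], spacing[2]};

  double dmax = *std::max_element(ref, ref + reference.size());
  if (dmax <= 0) stop("reference dose maximum must be positive");
  double cutoff = exclusion_fraction * dmax;

  std::vector<Offset> offs = build_offsets(step, radius, sp);
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.dist2 < b.dist2; });
  size_t noff = offs.size();
  double dta2 = dta * dta;

  NumericVector gamma(reference.size(), NA_REAL);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        long v = i + (long)n1 * (j + (long)n2 * k);
        double dr = ref[v];
        if (dr < cutoff) continue;              // excluded, stays NA
        double tol = dose_tol_pct / 100.0 * (global_norm ? dmax : dr);
        if (tol <= 0) continue;                 // non-positive local dose
        double best = R_PosInf;
        for (size_t m = 0; m < noff; ++m) {
          const Offset &o = offs[m];
          double dterm = o.dist2 / dta2;
          if (dterm >= best) break;             // sorted: nothing better remains
          double de;
          if (!sample(ev, n1, n2, n3, i, j, k, o, de)) continue;
          double dd = (de - dr) / tol;
          double g2 = dterm + dd * dd;
          if (g2 < best) best = g2;
        }
        gamma[v] = std::sqrt(best);
      }
  return gamma;
}

// -------------------------------------------------------------------------
// Exhaustive brute-force oracle: a literal transcription of the gamma
// definition. For every evaluated voxel it walks ALL lattice offsets inside
// the search sphere in raw loop order, recomputing position, distance and
// trilinear interpolation from scratch — no precomputation, no sorting, no
// pruning. Kept deliberately independent of the production code above.
// -------------------------------------------------------------------------

// [[Rcpp::export(name = ".gamma_exhaustive_cpp")]]
NumericVector gamma_exhaustive_cpp(NumericVector reference, NumericVector evaluated,
                                   IntegerVector dims, NumericVector spacing,
                                   double dose_tol_pct, double dta,
                                   double exclusion_fraction, double step,
                                   double radius, bool global_norm) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *ref = reference.begin();
  const double *ev = evaluated.begin();

  double dmax = ref[0];
  for (long t = 1; t < (long)reference.size(); ++t)
    if (ref[t] > dmax) dmax = ref[t];
  if (dmax <= 0) stop("reference dose maximum must be positive");
  double cutoff = exclusion_fraction * dmax;

  int nmax = (int)std::floor(radius / step + 1e-9);
  double r2 = radius * radius, dta2 = dta * dta;

  NumericVector gamma(reference.size(), NA_REAL);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        long v = i + (long)n1 * (j + (long)n2 * k);
        double dr = ref[v];
        if (dr < cutoff) continue;
        double tol = dose_tol_pct / 100.0 * (global_norm ? dmax : dr);
        if (tol <= 0) continue;
        double best = R_PosInf;
        for (int a = -nmax; a <= nmax; ++a)
          for (int b = -nmax; b <= nmax; ++b)
            for (int c = -nmax; c <= nmax; ++c) {
              double ox = a * step, oy = b * step, oz = c * step;
              double d2 = ox * ox + oy * oy + oz * oz;
              if (d2 > r2 + 1e-9) continue;
              // sample position in fractional voxel coordinates
              double px = i + ox / spacing[0];
              double py = j + oy / spacing[1];
              double pz = k + oz / spacing[2];
              double fx = std::floor(px), fy = std::floor(py), fz = std::floor(pz);
              int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
              double wx = px - fx, wy = py - fy, wz = pz - fz;
              int x1 = x0 + 1, y1 = y0 + 1, z1 = z0 + 1;
              if (wx < 1e-12) { x1 = x0; wx = 0.0; }
              if (wy < 1e-12) { y1 = y0; wy = 0.0; }
              if (wz < 1e-12) { z1 = z0; wz = 0.0; }
              if (x0 < 0 || x1 > n1 - 1 || y0 < 0 || y1 > n2 - 1 ||
                  z0 < 0 || z1 > n3 - 1)
                continue;
              long s0 = (long)n1, s1 = (long)n1 * n2;
              double de =
                (1 - wx) * (1 - wy) * (1 - wz) * ev[x0 + s0 * y0 + s1 * z0] +
                wx * (1 - wy) * (1 - wz) * ev[x1 + s0 * y0 + s1 * z0] +
                (1 - wx) * wy * (1 - wz) * ev[x0 + s0 * y1 + s1 * z0] +
                wx * wy * (1 - wz) * ev[x1 + s0 * y1 + s1 * z0] +
                (1 - wx) * (1 - wy) * wz * ev[x0 + s0 * y0 + s1 * z1] +
                wx * (1 - wy) * wz * ev[x1 + s0 * y0 + s1 * z1] +
                (1 - wx) * wy * wz * ev[x0 + s0 * y1 + s1 * z1] +
                wx * wy * wz * ev[x1 + s0 * y1 + s1 * z1];
              double dd = (de - dr) / tol;
              double g2 = d2 / dta2 + dd * dd;
              if (g2 < best) best = g2;
            }
        gamma[v] = std::sqrt(best);
      }
  return gamma;
}
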