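// Volume utilities: trilinear resampling between rectilinear grids and
// the gamma-index search with early termination (sorted offsets).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// locate q in strictly increasing coords s (length m): returns interval
// index i in [0, m-2] and weight w for linear interpolation; constant
// extrapolation outside.
static inline void locate(const std::vector<double>& s, double q, int& i,
                          double& w) {
  const int m = (int)s.size();
  if (q <= s[0]) { i = 0; w = 0.0; return; }
  if (q >= s[m - 1]) { i = m - 2; w = 1.0; return; }
  i = (int)(std::upper_bound(s.begin(), s.end(), q) - s.begin()) - 1;
  if (i > m - 2) i = m - 2;
  w = (q - s[i]) / (s[i + 1] - s[i]);
}

// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector src, NumericVector sx,
                                     NumericVector sy, NumericVector sz,
                                     NumericVector qx, NumericVector qy,
                                     NumericVector qz) {
  const int nx = sx.size(), ny = sy.size(), nz = sz.size();
  if ((R_xlen_t)nx * ny * nz != src.size())
    stop("source dims do not match coordinate lengths");
  std::vector<double> vx(sx.begin(), sx.end()), vy(sy.begin(), sy.end()),
      vz(sz.begin(), sz.end());
  const int mx = qx.size(), my = qy.size(), mz = qz.size();
  std::vector<int> ix(mx), iy(my), iz(mz);
  std::vector<double> wx(mx), wy(my), wz(mz);
  for (int i = 0; i < mx; ++i) locate(vx, qx[i], ix[i], wx[i]);
  for (int j = 0; j < my; ++j) locate(vy, qy[j], iy[j], wy[j]);
  for (int k = 0; k < mz; ++k) locate(vz, qz[k], iz[k], wz[k]);
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* a = src.begin();
  R_xlen_t pos = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++pos) {
        const R_xlen_t base =
            (R_xlen_t)ix[i] + (R_xlen_t)nx * (iy[j] + (R_xlen_t)ny * iz[k]);
        const double u = wx[i], v = wy[j], w = wz[k];
        const double c000 = a[base], c100 = a[base + 1];
        const double c010 = a[base + nx], c110 = a[base + nx + 1];
        const R_xlen_t bz = base + (R_xlen_t)nx * ny;
        const double c001 = a[bz], c101 = a[bz + 1];
        const double c011 = a[bz + nx], c111 = a[bz + nx + 1];
        out[pos] =
            (1 - w) * ((1 - v) * ((1 - u) * c000 + u * c100) +
                       v * ((1 - u) * c010 + u * c110)) +
            w * ((1 - v) * ((1 - u) * c001 + u * c101) +
                 v * ((1 - u) * c011 + u * c111));
      }
  return out;
}

struct Offset {
  int di, dj, dk;
  double dist;
};

// gamma search: reference voxels at coordinates (rx, ry, rz) (any
// rectilinear grid), evaluated samples on a uniform grid with origin e0
// and spacing es. For each VOI reference voxel the generalized Gamma is
// minimized over evaluated samples within search_radius, visiting
// offsets sorted by distance and stopping once the distance term alone
// exceeds the current minimum (accounting for sub-spacing misalignment).
// [[Rcpp::export]]
NumericVector gamma_search_cpp(NumericVector ref, NumericVector rx,
                               NumericVector ry, NumericVector rz,
                               LogicalVector voi, NumericVector evalv,
                               IntegerVector edims, NumericVector e0,
                               NumericVector es, NumericVector dd_abs,
                               double dta, double search_radius) {
  const int nx = rx.size(), ny = ry.size(), nz = rz.size();
  if ((R_xlen_t)nx * ny * nz != ref.size()) stop("reference dims mismatch");
  const int ex = edims[0], ey = edims[1], ez = edims[2];
  if ((R_xlen_t)ex * ey * ez != evalv.size()) stop("evaluated dims mismatch");

  // offsets within search_radius + one spacing of slack, sorted by distance
  std::vector<Offset> offs;
  const int mi = (int)std::ceil(search_radius / es[0]) + 1;
  const int mj = (int)std::ceil(search_radius / es[1]) + 1;
  const int mk = (int)std::ceil(search_radius / es[2]) + 1;
  const double halfdiag = 0.5 * std::sqrt(es[0] * es[0] + es[1] * es[1] +
                                          es[2] * es[2]);
  for (int dk = -mk; dk <= mk; ++dk)
    for (int dj = -mj; dj <= mj; ++dj)
      for (int di = -mi; di <= mi; ++di) {
        const double d = std::sqrt(di * es[0] * di * es[0] +
                                   dj * es[1] * dj * es[1] +
                                   dk * es[2] * dk * es[2]);
        if (d <= search_radius + halfdiag) offs.push_back({di, dj, dk, d});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.dist < b.dist; });

  const double* ev = evalv.begin();
  const bool dd_per_voxel = dd_abs.size() > 1;
  if (dd_per_voxel && dd_abs.size() != ref.size())
    stop("dd_abs must be scalar or one value per reference voxel");
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t pos = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++pos) {
        if (!voi[pos]) { out[pos] = NA_REAL; continue; }
        const double px = rx[i], py = ry[j], pz = rz[k];
        const double fbx = (px - e0[0]) / es[0];
        const double fby = (py - e0[1]) / es[1];
        const double fbz = (pz - e0[2]) / es[2];
        const int bx = (int)std::lround(fbx);
        const int by = (int)std::lround(fby);
        const int bz = (int)std::lround(fbz);
        const double sref = ref[pos];
        const double dd = dd_per_voxel ? dd_abs[pos] : dd_abs[0];
        double g2min = R_PosInf;
        for (const Offset& o : offs) {
          const double dlow = o.dist - halfdiag;
          if (dlow > 0 && dlow * dlow / (dta * dta) >= g2min) break;
          const int ii = bx + o.di, jj = by + o.dj, kk = bz + o.dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= ex || jj >= ey || kk >= ez)
            continue;
          const double ddx = (ii - fbx) * es[0];
          const double ddy = (jj - fby) * es[1];
          const double ddz = (kk - fbz) * es[2];
          const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 > search_radius * search_radius) continue;
          const double diff =
              (sref - ev[(R_xlen_t)ii + (R_xlen_t)ex * (jj + (R_xlen_t)ey * kk)]) /
              dd;
          const double g2 = diff * diff + d2 / (dta * dta);
          if (g2 < g2min) g2min = g2;
        }
        out[pos] = std::sqrt(g2min);
      }
  return out;
}
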