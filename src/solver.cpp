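// Electro-quasistatic stencil kernels on a rectilinear node grid.
//
// Unknowns are node potentials; gx/gy/gz hold the complex edge
// conductances between adjacent nodes (dims (nx-1,ny,nz) etc.).
// Dirichlet nodes (dmask != 0) are held at dvals; the operator acts on
// free nodes only. extra_diag adds a per-node diagonal term (used by the
// implicit bioheat step: capacity/dt + perfusion).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline cplx cv(const Rcomplex& z) { return cplx(z.r, z.i); }

struct Stencil {
  const Rcomplex *gx, *gy, *gz, *extra;
  int nx, ny, nz;
  inline int id(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline cplx GX(int i, int j, int k) const { return cv(gx[i + (nx - 1) * (j + ny * k)]); }
  inline cplx GY(int i, int j, int k) const { return cv(gy[i + nx * (j + (ny - 1) * k)]); }
  inline cplx GZ(int i, int j, int k) const { return cv(gz[i + nx * (j + ny * k)]); }
};

// y = L(x) over all nodes: y_u = sum_v G_uv (x_u - x_v) + extra_u x_u
static void apply_full(const Stencil& S, const cplx* x, cplx* y) {
  const int nx = S.nx, ny = S.ny, nz = S.nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int u = S.id(i, j, k);
        cplx acc = cv(S.extra[u]) * x[u];
        if (i > 0)      { cplx g = S.GX(i - 1, j, k); acc += g * (x[u] - x[u - 1]); }
        if (i < nx - 1) { cplx g = S.GX(i, j, k);     acc += g * (x[u] - x[u + 1]); }
        if (j > 0)      { cplx g = S.GY(i, j - 1, k); acc += g * (x[u] - x[u - nx]); }
        if (j < ny - 1) { cplx g = S.GY(i, j, k);     acc += g * (x[u] - x[u + nx]); }
        if (k > 0)      { cplx g = S.GZ(i, j, k - 1); acc += g * (x[u] - x[u - nx * ny]); }
        if (k < nz - 1) { cplx g = S.GZ(i, j, k);     acc += g * (x[u] - x[u + nx * ny]); }
        y[u] = acc;
      }
}

// y = A x on free nodes (x and y zero on Dirichlet nodes)
static void apply_free(const Stencil& S, const int* dmask, const cplx* x,
                       cplx* y) {
  const int nx = S.nx, ny = S.ny, nz = S.nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int u = S.id(i, j, k);
        if (dmask[u]) { y[u] = 0.0; continue; }
        cplx acc = cv(S.extra[u]) * x[u];
        if (i > 0)      { cplx g = S.GX(i - 1, j, k); acc += g * x[u]; if (!dmask[u - 1]) acc -= g * x[u - 1]; }
        if (i < nx - 1) { cplx g = S.GX(i, j, k);     acc += g * x[u]; if (!dmask[u + 1]) acc -= g * x[u + 1]; }
        if (j > 0)      { cplx g = S.GY(i, j - 1, k); acc += g * x[u]; if (!dmask[u - nx]) acc -= g * x[u - nx]; }
        if (j < ny - 1) { cplx g = S.GY(i, j, k);     acc += g * x[u]; if (!dmask[u + nx]) acc -= g * x[u + nx]; }
        if (k > 0)      { cplx g = S.GZ(i, j, k - 1); acc += g * x[u]; if (!dmask[u - nx * ny]) acc -= g * x[u - nx * ny]; }
        if (k < nz - 1) { cplx g = S.GZ(i, j, k);     acc += g * x[u]; if (!dmask[u + nx * ny]) acc -= g * x[u + nx * ny]; }
        y[u] = acc;
      }
}

// SSOR preconditioner solve M z = r (free nodes; z = 0 on Dirichlet).
// invdiag holds 1/diag to avoid complex divisions in the sweeps.
static void ssor_solve(const Stencil& S, const int* dmask, const cplx* diag,
                       const cplx* invdiag, double om, const cplx* r,
                       cplx* z) {
  const int nx = S.nx, ny = S.ny, nz = S.nz;
  // forward sweep: (D/om + L) y = r, store y in z
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int u = S.id(i, j, k);
        if (dmask[u]) { z[u] = 0.0; continue; }
        cplx acc = r[u];
        if (i > 0 && !dmask[u - 1])           acc += S.GX(i - 1, j, k) * z[u - 1];
        if (j > 0 && !dmask[u - nx])          acc += S.GY(i, j - 1, k) * z[u - nx];
        if (k > 0 && !dmask[u - nx * ny])     acc += S.GZ(i, j, k - 1) * z[u - nx * ny];
        z[u] = om * acc * invdiag[u];
      }
  // scale by D/om, then backward sweep (D/om + U) z = w
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        const int u = S.id(i, j, k);
        if (dmask[u]) continue;
        cplx acc = diag[u] * z[u] / om;
        if (i < nx - 1 && !dmask[u + 1])       acc += S.GX(i, j, k) * z[u + 1];
        if (j < ny - 1 && !dmask[u + nx])      acc += S.GY(i, j, k) * z[u + nx];
        if (k < nz - 1 && !dmask[u + nx * ny]) acc += S.GZ(i, j, k) * z[u + nx * ny];
        z[u] = om * acc * invdiag[u];
      }
}

static Stencil make_stencil(const ComplexVector& gx, const ComplexVector& gy,
                            const ComplexVector& gz,
                            const ComplexVector& extra,
                            const IntegerVector& nn) {
  Stencil S;
  S.gx = gx.begin(); S.gy = gy.begin(); S.gz = gz.begin();
  S.extra = extra.begin();
  S.nx = nn[0]; S.ny = nn[1]; S.nz = nn[2];
  return S;
}

// [[Rcpp::export]]
ComplexVector eqs_apply_cpp(ComplexVector gx, ComplexVector gy,
                            ComplexVector gz, ComplexVector extra,
                            ComplexVector x, IntegerVector nn) {
  Stencil S = make_stencil(gx, gy, gz, extra, nn);
  const R_xlen_t n = (R_xlen_t)S.nx * S.ny * S.nz;
  ComplexVector out(n);
  apply_full(S, reinterpret_cast<const cplx*>(x.begin()),
             reinterpret_cast<cplx*>(out.begin()));
  return out;
}

// [[Rcpp::export]]
List eqs_bicgstab_cpp(ComplexVector gx, ComplexVector gy, ComplexVector gz,
                      ComplexVector extra, ComplexVector rhs,
                      IntegerVector dmask, ComplexVector dvals,
                      ComplexVector x0, IntegerVector nn,
                      double tol, int maxit, double ssor_omega) {
  Stencil S = make_stencil(gx, gy, gz, extra, nn);
  const int nx = S.nx, ny = S.ny, nz = S.nz;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* dm = dmask.begin();

  std::vector<cplx> diag(n), invdiag(n), b(n), x(n), r(n), rh(n), p(n),
      v(n), ph(n), s(n), sh(n), t(n);

  // diagonal (all incident edges + extra) and Dirichlet lifting of rhs
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int u = S.id(i, j, k);
        cplx d = cv(extra[u]), bb = cv(rhs[u]);
        if (i > 0)      { cplx g = S.GX(i - 1, j, k); d += g; if (dm[u - 1]) bb += g * cv(dvals[u - 1]); }
        if (i < nx - 1) { cplx g = S.GX(i, j, k);     d += g; if (dm[u + 1]) bb += g * cv(dvals[u + 1]); }
        if (j > 0)      { cplx g = S.GY(i, j - 1, k); d += g; if (dm[u - nx]) bb += g * cv(dvals[u - nx]); }
        if (j < ny - 1) { cplx g = S.GY(i, j, k);     d += g; if (dm[u + nx]) bb += g * cv(dvals[u + nx]); }
        if (k > 0)      { cplx g = S.GZ(i, j, k - 1); d += g; if (dm[u - nx * ny]) bb += g * cv(dvals[u - nx * ny]); }
        if (k < nz - 1) { cplx g = S.GZ(i, j, k);     d += g; if (dm[u + nx * ny]) bb += g * cv(dvals[u + nx * ny]); }
        diag[u] = d;
        b[u] = dm[u] ? cplx(0.0) : bb;
        x[u] = dm[u] ? cplx(0.0) : cv(x0[u]);
        if (!dm[u] && d == cplx(0.0))
          stop("singular diagonal at a free node (isolated node?)");
        invdiag[u] = dm[u] ? cplx(0.0) : 1.0 / d;
      }

  double bnorm = 0.0;
  for (R_xlen_t u = 0; u < n; ++u) bnorm += std::norm(b[u]);
  bnorm = std::sqrt(bnorm);

  auto fill_solution = [&](double relres, int iters, bool conv) {
    ComplexVector out(n);
    for (R_xlen_t u = 0; u < n; ++u) {
      cplx val = dm[u] ? cv(dvals[u]) : x[u];
      out[u].r = val.real(); out[u].i = val.imag();
    }
    return List::create(_["x"] = out, _["relres"] = relres,
                        _["iterations"] = iters, _["converged"] = conv);
  };

  if (bnorm == 0.0) {
    std::fill(x.begin(), x.end(), cplx(0.0));
    return fill_solution(0.0, 0, true);
  }

  apply_free(S, dm, x.data(), r.data());
  for (R_xlen_t u = 0; u < n; ++u) r[u] = b[u] - r[u];
  rh = r;
  cplx rho(1.0), alpha(1.0), omega(1.0);
  std::fill(p.begin(), p.end(), cplx(0.0));
  std::fill(v.begin(), v.end(), cplx(0.0));

  double relres = 0.0;
  {
    double rn = 0.0;
    for (R_xlen_t u = 0; u < n; ++u) rn += std::norm(r[u]);
    relres = std::sqrt(rn) / bnorm;
  }
  if (relres <= tol) return fill_solution(relres, 0, true);

  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    cplx rho1(0.0);
    for (R_xlen_t u = 0; u < n; ++u) rho1 += std::conj(rh[u]) * r[u];
    if (rho1 == cplx(0.0)) break;
    if (it == 1) {
      p = r;
    } else {
      cplx beta = (rho1 / rho) * (alpha / omega);
      for (R_xlen_t u = 0; u < n; ++u)
        p[u] = r[u] + beta * (p[u] - omega * v[u]);
    }
    ssor_solve(S, dm, diag.data(), invdiag.data(), ssor_omega, p.data(), ph.data());
    apply_free(S, dm, ph.data(), v.data());
    cplx rv(0.0);
    for (R_xlen_t u = 0; u < n; ++u) rv += std::conj(rh[u]) * v[u];
    if (rv == cplx(0.0)) break;
    alpha = rho1 / rv;
    for (R_xlen_t u = 0; u < n; ++u) s[u] = r[u] - alpha * v[u];
    double sn = 0.0;
    for (R_xlen_t u = 0; u < n; ++u) sn += std::norm(s[u]);
    if (std::sqrt(sn) / bnorm <= tol) {
      for (R_xlen_t u = 0; u < n; ++u) x[u] += alpha * ph[u];
      relres = std::sqrt(sn) / bnorm;
      return fill_solution(relres, it, true);
    }
    ssor_solve(S, dm, diag.data(), invdiag.data(), ssor_omega, s.data(), sh.data());
    apply_free(S, dm, sh.data(), t.data());
    cplx ts(0.0); double tt = 0.0;
    for (R_xlen_t u = 0; u < n; ++u) {
      ts += std::conj(t[u]) * s[u];
      tt += std::norm(t[u]);
    }
    if (tt == 0.0) break;
    omega = ts / tt;
    for (R_xlen_t u = 0; u < n; ++u) {
      x[u] += alpha * ph[u] + omega * sh[u];
      r[u] = s[u] - omega * t[u];
    }
    double rn = 0.0;
    for (R_xlen_t u = 0; u < n; ++u) rn += std::norm(r[u]);
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) return fill_solution(relres, it, true);
    if (omega == cplx(0.0)) break;
    rho = rho1;
  }
  // recompute true residual before reporting
  apply_free(S, dm, x.data(), t.data());
  double rn = 0.0;
  for (R_xlen_t u = 0; u < n; ++u) rn += std::norm(b[u] - t[u]);
  relres = std::sqrt(rn) / bnorm;
  return fill_solution(relres, it > maxit ? maxit : it, relres <= tol);
}
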