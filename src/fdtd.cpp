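// 2D velocity-stress staggered-grid elastodynamic FDTD (plane strain),
// split-field PML on all four sides. Grid layout (z = depth = rows,
// x = lateral = cols), cell size dx in both directions:
//   sxx, szz at integer points (i, j)
//   sxz at (i+1/2, j+1/2)        valid i < nz-1, j < nx-1
//   vx  at (i, j+1/2)            valid j < nx-1
//   vz  at (i+1/2, j)            valid i < nz-1
// Fields outside the domain are zero (rigid outer edge; with PML the
// wave is damped before reaching it). Each split component is damped by
// the profile of its own derivative direction.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double harm4(double a, double b, double c, double d) {
  if (a <= 0 || b <= 0 || c <= 0 || d <= 0) return 0.0;
  return 4.0 / (1.0 / a + 1.0 / b + 1.0 / c + 1.0 / d);
}

// [[Rcpp::export]]
List fdtd_kernel(IntegerMatrix mat, NumericVector c11m, NumericVector c12m,
                 NumericVector c33m, NumericVector rhom, double dx,
                 double dt, int nsteps, NumericVector src, int src_row,
                 IntegerVector src_cols, IntegerVector rec_rows,
                 IntegerVector rec_cols, int npml_z, int npml_x, double d0,
                 bool record_energy, double instab_limit) {
  const int nz = mat.nrow(), nx = mat.ncol();
  const int nrec = rec_rows.size();
  const size_t N = (size_t)nz * nx;
  auto at = [nz](int i, int j) { return (size_t)i + (size_t)j * nz; };

  // per-cell material constants
  std::vector<double> c11(N), c12(N), mu_c(N), rho_c(N);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i) {
      int m = mat(i, j) - 1;
      c11[at(i, j)] = c11m[m];
      c12[at(i, j)] = c12m[m];
      mu_c[at(i, j)] = c33m[m];
      rho_c[at(i, j)] = rhom[m];
    }
  // staggered effective media
  std::vector<double> bx(N), bz(N), mu_s(N);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i) {
      size_t k = at(i, j);
      double rx = (j < nx - 1) ? 0.5 * (rho_c[k] + rho_c[at(i, j + 1)]) : rho_c[k];
      double rz = (i < nz - 1) ? 0.5 * (rho_c[k] + rho_c[at(i + 1, j)]) : rho_c[k];
      bx[k] = 1.0 / rx;
      bz[k] = 1.0 / rz;
      if (i < nz - 1 && j < nx - 1)
        mu_s[k] = harm4(mu_c[k], mu_c[at(i + 1, j)], mu_c[at(i, j + 1)],
                        mu_c[at(i + 1, j + 1)]);
      else mu_s[k] = 0.0;
    }

  // PML damping profiles, quadratic ramp, at integer and half positions
  std::vector<double> dzp(nz, 0.0), dzh(nz, 0.0), dxp(nx, 0.0), dxh(nx, 0.0);
  if (npml_z > 0) {
    double L = npml_z * dx;
    auto prof = [&](double u) {            // u = depth into PML, meters
      if (u <= 0) return 0.0;
      double r = u / L;
      return d0 * r * r;
    };
    for (int i = 0; i < nz; ++i) {
      double zi = i * dx, zh = (i + 0.5) * dx;
      double lo = npml_z * dx, hi = (nz - 1 - npml_z) * dx;
      dzp[i] = prof(lo - zi) + prof(zi - hi);
      dzh[i] = prof(lo - zh) + prof(zh - hi);
    }
  }
  if (npml_x > 0) {
    double L = npml_x * dx;
    auto prof = [&](double u) {
      if (u <= 0) return 0.0;
      double r = u / L;
      return d0 * r * r;
    };
    for (int j = 0; j < nx; ++j) {
      double xj = j * dx, xh = (j + 0.5) * dx;
      double lo = npml_x * dx, hi = (nx - 1 - npml_x) * dx;
      dxp[j] = prof(lo - xj) + prof(xj - hi);
      dxh[j] = prof(lo - xh) + prof(xh - hi);
    }
  }

  // split fields
  std::vector<double> vx_x(N, 0), vx_z(N, 0), vz_x(N, 0), vz_z(N, 0),
      sxx_x(N, 0), sxx_z(N, 0), szz_x(N, 0), szz_z(N, 0),
      sxz_x(N, 0), sxz_z(N, 0);
  std::vector<double> vx_o, vz_o;           // previous half-step velocities
  if (record_energy) { vx_o.assign(N, 0); vz_o.assign(N, 0); }

  NumericMatrix rec(nsteps, nrec);
  NumericVector e_tot(record_energy ? nsteps : 0),
      e_kin(record_energy ? nsteps : 0), e_str(record_energy ? nsteps : 0);
  const double idx = 1.0 / dx;
  double srcmax = 0.0;
  for (int n = 0; n < src.size(); ++n)
    srcmax = std::max(srcmax, std::fabs(src[n]));
  if (srcmax == 0.0) srcmax = 1.0;

  for (int n = 0; n < nsteps; ++n) {
    if (record_energy)
      for (size_t k = 0; k < N; ++k) {
        vx_o[k] = vx_x[k] + vx_z[k];
        vz_o[k] = vz_x[k] + vz_z[k];
      }

    // --- velocity update (uses sigma^n) ---
    for (int j = 0; j < nx - 1; ++j) {
      double axh = 0.5 * dt * dxh[j];
      for (int i = 0; i < nz; ++i) {
        size_t k = at(i, j);
        double az = 0.5 * dt * dzp[i];
        double dsxx = ((sxx_x[at(i, j + 1)] + sxx_z[at(i, j + 1)]) -
                       (sxx_x[k] + sxx_z[k])) * idx;
        double up = (i > 0) ? (sxz_x[at(i - 1, j)] + sxz_z[at(i - 1, j)]) : 0.0;
        double dn = (i < nz - 1) ? (sxz_x[k] + sxz_z[k]) : 0.0;
        double dsxz = (dn - up) * idx;
        vx_x[k] = (vx_x[k] * (1 - axh) + dt * bx[k] * dsxx) / (1 + axh);
        vx_z[k] = (vx_z[k] * (1 - az) + dt * bx[k] * dsxz) / (1 + az);
      }
    }
    for (int j = 0; j < nx; ++j) {
      double ax = 0.5 * dt * dxp[j];
      for (int i = 0; i < nz - 1; ++i) {
        size_t k = at(i, j);
        double azh = 0.5 * dt * dzh[i];
        double dszz = ((szz_x[at(i + 1, j)] + szz_z[at(i + 1, j)]) -
                       (szz_x[k] + szz_z[k])) * idx;
        double lf = (j > 0) ? (sxz_x[at(i, j - 1)] + sxz_z[at(i, j - 1)]) : 0.0;
        double rt = (j < nx - 1) ? (sxz_x[k] + sxz_z[k]) : 0.0;
        double dsxz = (rt - lf) * idx;
        vz_x[k] = (vz_x[k] * (1 - ax) + dt * bz[k] * dsxz) / (1 + ax);
        vz_z[k] = (vz_z[k] * (1 - azh) + dt * bz[k] * dszz) / (1 + azh);
      }
    }

    // --- energy at integer time n: strain(sigma^n) + rho v^{n-1/2} v^{n+1/2}
    if (record_energy) {
      double ek = 0.0, es = 0.0;
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < nz; ++i) {
          size_t k = at(i, j);
          double vxn = vx_x[k] + vx_z[k], vzn = vz_x[k] + vz_z[k];
          double rx = 1.0 / bx[k], rz = 1.0 / bz[k];
          ek += 0.5 * (rx * vxn * vx_o[k] + rz * vzn * vz_o[k]);
          double a = c11[k], b = c12[k];
          double det = a * a - b * b;
          double sxx = sxx_x[k] + sxx_z[k], szz = szz_x[k] + szz_z[k];
          es += 0.5 * (a * (sxx * sxx + szz * szz) - 2 * b * sxx * szz) / det;
          double sxz = sxz_x[k] + sxz_z[k];
          if (mu_s[k] > 0) es += 0.5 * sxz * sxz / mu_s[k];
        }
      e_kin[n] = ek * dx * dx;
      e_str[n] = es * dx * dx;
      e_tot[n] = e_kin[n] + e_str[n];
    }

    // --- stress update (uses v^{n+1/2}) ---
    for (int j = 0; j < nx; ++j) {
      double ax = 0.5 * dt * dxp[j];
      for (int i = 0; i < nz; ++i) {
        size_t k = at(i, j);
        double az = 0.5 * dt * dzp[i];
        double vxr = (j < nx - 1) ? (vx_x[k] + vx_z[k]) : 0.0;
        double vxl = (j > 0) ? (vx_x[at(i, j - 1)] + vx_z[at(i, j - 1)]) : 0.0;
        double dvx = (vxr - vxl) * idx;
        double vzd = (i < nz - 1) ? (vz_x[k] + vz_z[k]) : 0.0;
        double vzu = (i > 0) ? (vz_x[at(i - 1, j)] + vz_z[at(i - 1, j)]) : 0.0;
        double dvz = (vzd - vzu) * idx;
        sxx_x[k] = (sxx_x[k] * (1 - ax) + dt * c11[k] * dvx) / (1 + ax);
        sxx_z[k] = (sxx_z[k] * (1 - az) + dt * c12[k] * dvz) / (1 + az);
        szz_x[k] = (szz_x[k] * (1 - ax) + dt * c12[k] * dvx) / (1 + ax);
        szz_z[k] = (szz_z[k] * (1 - az) + dt * c11[k] * dvz) / (1 + az);
      }
    }
    for (int j = 0; j < nx - 1; ++j) {
      double axh = 0.5 * dt * dxh[j];
      for (int i = 0; i < nz - 1; ++i) {
        size_t k = at(i, j);
        if (mu_s[k] <= 0) continue;
        double azh = 0.5 * dt * dzh[i];
        double dvzx = ((vz_x[at(i, j + 1)] + vz_z[at(i, j + 1)]) -
                       (vz_x[k] + vz_z[k])) * idx;
        double dvxz = ((vx_x[at(i + 1, j)] + vx_z[at(i + 1, j)]) -
                       (vx_x[k] + vx_z[k])) * idx;
        sxz_x[k] = (sxz_x[k] * (1 - axh) + dt * mu_s[k] * dvzx) / (1 + axh);
        sxz_z[k] = (sxz_z[k] * (1 - azh) + dt * mu_s[k] * dvxz) / (1 + azh);
      }
    }

    // --- pressure source: isotropic normal-stress injection ---
    if (n < src.size() && src[n] != 0.0) {
      double w = src[n];
      for (int q = 0; q < src_cols.size(); ++q) {
        size_t k = at(src_row, src_cols[q]);
        sxx_x[k] += 0.5 * w; sxx_z[k] += 0.5 * w;
        szz_x[k] += 0.5 * w; szz_z[k] += 0.5 * w;
      }
    }

    // --- record pressure = -(sxx+szz)/2 ---
    for (int r = 0; r < nrec; ++r) {
      size_t k = at(rec_rows[r], rec_cols[r]);
      rec(n, r) = -0.5 * (sxx_x[k] + sxx_z[k] + szz_x[k] + szz_z[k]);
    }

    if ((n & 63) == 0) {
      double pk = 0.0;
      for (int r = 0; r < nrec; ++r) pk = std::max(pk, std::fabs(rec(n, r)));
      size_t mid = at(nz / 2, nx / 2);
      pk = std::max(pk, std::fabs(sxx_x[mid] + sxx_z[mid] + szz_x[mid] + szz_z[mid]));
      if (!std::isfinite(pk) || pk > instab_limit * srcmax)
        stop("fdtd instability: field amplitude exceeded %g x source peak at step %d",
             instab_limit, n);
    }
  }

  return List::create(_["pressure"] = rec, _["energy"] = e_tot,
                      _["kinetic"] = e_kin, _["strain"] = e_str);
}
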