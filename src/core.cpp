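#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Phase-factor tables e^{i 2 pi n x / L} for n = 0..nmax, one per axis.
static void phase_tables(const Rcpp::NumericMatrix& pos, int axis, double L,
                         int nmax, std::vector<double>& re,
                         std::vector<double>& im) {
  const int n = pos.nrow();
  re.assign((size_t)(nmax + 1) * n, 0.0);
  im.assign((size_t)(nmax + 1) * n, 0.0);
  for (int i = 0; i < n; ++i) { re[i] = 1.0; im[i] = 0.0; }
  if (nmax == 0) return;
  for (int i = 0; i < n; ++i) {
    const double a = 2.0 * M_PI * pos(i, axis) / L;
    const double c = std::cos(a), s = std::sin(a);
    re[n + i] = c; im[n + i] = s;
    for (int m = 2; m <= nmax; ++m) {
      re[(size_t)m * n + i] = re[(size_t)(m - 1) * n + i] * c -
                              im[(size_t)(m - 1) * n + i] * s;
      im[(size_t)m * n + i] = re[(size_t)(m - 1) * n + i] * s +
                              im[(size_t)(m - 1) * n + i] * c;
    }
  }
}

// per-particle phase e^{i k.r} for one k (integer triple), from the tables
static inline void k_phase(int i, int n, int nx, int ny, int nz,
                           const std::vector<double>& rx,
                           const std::vector<double>& ix,
                           const std::vector<double>& ry,
                           const std::vector<double>& iy,
                           const std::vector<double>& rz,
                           const std::vector<double>& iz,
                           double& pre, double& pim) {
  const int ax = nx < 0 ? -nx : nx, ay = ny < 0 ? -ny : ny,
            az = nz < 0 ? -nz : nz;
  double xr = rx[(size_t)ax * n + i], xi = ix[(size_t)ax * n + i];
  if (nx < 0) xi = -xi;
  double yr = ry[(size_t)ay * n + i], yi = iy[(size_t)ay * n + i];
  if (ny < 0) yi = -yi;
  double zr = rz[(size_t)az * n + i], zi = iz[(size_t)az * n + i];
  if (nz < 0) zi = -zi;
  const double tr = xr * yr - xi * yi, ti = xr * yi + xi * yr;
  pre = tr * zr - ti * zi;
  pim = tr * zi + ti * zr;
}

// Reciprocal-space field of the slowly varying Coulomb component at a set of
// evaluation points. nmat holds the integer k-grid indices (k = 2 pi n / L);
// coeff[k] must hold (4*pi*ke/V) * exp(-k^2 sigma^2/4) / k^2 so that
// E(p) = sum_k coeff_k * kvec * Im( conj(S_k) * exp(i k.p) ), with
// S_k = sum_j q_j exp(i k.r_j). The k = 0 term is excluded by construction
// (tinfoil boundary conditions).
// [[Rcpp::export]]
NumericMatrix kspace_field_cpp(NumericMatrix src, NumericVector q,
                               NumericMatrix pts, IntegerMatrix nmat,
                               NumericVector L, NumericVector coeff) {
  const int ns = src.nrow(), np = pts.nrow(), nk = nmat.nrow();
  int nmax[3] = {0, 0, 0};
  for (int k = 0; k < nk; ++k)
    for (int d = 0; d < 3; ++d) {
      const int a = nmat(k, d) < 0 ? -nmat(k, d) : nmat(k, d);
      if (a > nmax[d]) nmax[d] = a;
    }
  std::vector<double> srx, six, sry, siy, srz, siz;
  phase_tables(src, 0, L[0], nmax[0], srx, six);
  phase_tables(src, 1, L[1], nmax[1], sry, siy);
  phase_tables(src, 2, L[2], nmax[2], srz, siz);
  std::vector<double> prx, pix, pry, piy, prz, piz;
  phase_tables(pts, 0, L[0], nmax[0], prx, pix);
  phase_tables(pts, 1, L[1], nmax[1], pry, piy);
  phase_tables(pts, 2, L[2], nmax[2], prz, piz);
  NumericMatrix E(np, 3);
  for (int k = 0; k < nk; ++k) {
    const int nx = nmat(k, 0), ny = nmat(k, 1), nz = nmat(k, 2);
    double Sre = 0.0, Sim = 0.0, pre, pim;
    for (int j = 0; j < ns; ++j) {
      k_phase(j, ns, nx, ny, nz, srx, six, sry, siy, srz, siz, pre, pim);
      Sre += q[j] * pre; Sim += q[j] * pim;
    }
    const double kx = 2.0 * M_PI * nx / L[0];
    const double ky = 2.0 * M_PI * ny / L[1];
    const double kz = 2.0 * M_PI * nz / L[2];
    for (int p = 0; p < np; ++p) {
      k_phase(p, np, nx, ny, nz, prx, pix, pry, piy, prz, piz, pre, pim);
      const double w = coeff[k] * (Sre * pim - Sim * pre);
      E(p, 0) += w * kx; E(p, 1) += w * ky; E(p, 2) += w * kz;
    }
  }
  return E;
}

// Reciprocal-space energy and forces of the v1 interaction among a set of
// charges: U = 0.5 * sum_k coeff_k |S_k|^2, F_i = q_i E(r_i). The (constant)
// self-interaction is included in the energy; it exerts no force.
// [[Rcpp::export]]
List kspace_coulomb_cpp(NumericMatrix pos, NumericVector q,
                        IntegerMatrix nmat, NumericVector L,
                        NumericVector coeff) {
  const int n = pos.nrow(), nk = nmat.nrow();
  int nmax[3] = {0, 0, 0};
  for (int k = 0; k < nk; ++k)
    for (int d = 0; d < 3; ++d) {
      const int a = nmat(k, d) < 0 ? -nmat(k, d) : nmat(k, d);
      if (a > nmax[d]) nmax[d] = a;
    }
  std::vector<double> rx, ix, ry, iy, rz, iz;
  phase_tables(pos, 0, L[0], nmax[0], rx, ix);
  phase_tables(pos, 1, L[1], nmax[1], ry, iy);
  phase_tables(pos, 2, L[2], nmax[2], rz, iz);
  double U = 0.0;
  NumericMatrix F(n, 3);
  std::vector<double> pre_v(n), pim_v(n);
  for (int k = 0; k < nk; ++k) {
    const int nx = nmat(k, 0), ny = nmat(k, 1), nz = nmat(k, 2);
    double Sre = 0.0, Sim = 0.0;
    for (int j = 0; j < n; ++j) {
      k_phase(j, n, nx, ny, nz, rx, ix, ry, iy, rz, iz, pre_v[j], pim_v[j]);
      Sre += q[j] * pre_v[j]; Sim += q[j] * pim_v[j];
    }
    U += 0.5 * coeff[k] * (Sre * Sre + Sim * Sim);
    const double kx = 2.0 * M_PI * nx / L[0];
    const double ky = 2.0 * M_PI * ny / L[1];
    const double kz = 2.0 * M_PI * nz / L[2];
    for (int i = 0; i < n; ++i) {
      const double w = q[i] * coeff[k] * (Sre * pim_v[i] - Sim * pre_v[i]);
      F(i, 0) += w * kx; F(i, 1) += w * ky; F(i, 2) += w * kz;
    }
  }
  return List::create(Named("energy") = U, Named("forces") = F);
}

// Real-space part of the Ewald-split Coulomb interaction with intramolecular
// exclusions. Pairs on different molecules interact through
// ke*qq*erfc(r/sigma)/r inside rcut. Intramolecular pairs: with
// intra_mode = 0 the reciprocal-space v1 contribution is subtracted (so
// intramolecular Coulomb vanishes in total once the k-space part is added);
// with intra_mode = 1 they are skipped entirely (short-range-only system
// with no reciprocal part). v1 is regular at r = 0, so coincident
// intramolecular charges are allowed.
// [[Rcpp::export]]
List realspace_coulomb_cpp(NumericMatrix pos, NumericVector q,
                           IntegerVector mol, NumericVector L,
                           double sigma, double rcut, double ke,
                           int intra_mode = 0) {
  const int n = pos.nrow();
  const double rcut2 = rcut * rcut;
  const double twosp = 2.0 / (std::sqrt(M_PI) * sigma);
  double U = 0.0;
  NumericMatrix F(n, 3);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= L[0] * std::nearbyint(dx / L[0]);
      dy -= L[1] * std::nearbyint(dy / L[1]);
      dz -= L[2] * std::nearbyint(dz / L[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const bool intra = (mol[i] == mol[j]);
      if (intra && intra_mode == 1) continue;
      if (!intra && r2 > rcut2) continue;
      const double qq = ke * q[i] * q[j];
      double fs = 0.0;  // force magnitude / r along +d (on i)
      if (!intra) {
        const double r = std::sqrt(r2);
        const double x = r / sigma;
        const double er = std::erfc(x);
        U += qq * er / r;
        fs = qq * (er / r2 + twosp * std::exp(-x * x) / r) / r;
      } else {
        // subtract the v1 interaction (regular at r = 0)
        if (r2 < 1e-16) {
          U -= qq * twosp;  // v1(0) = 2/(sigma sqrt(pi)); zero force
        } else {
          const double r = std::sqrt(r2);
          const double x = r / sigma;
          const double ef = std::erf(x);
          U -= qq * ef / r;
          fs = -qq * (ef / r2 - twosp * std::exp(-x * x) / r) / r;
        }
      }
      F(i, 0) += fs * dx; F(i, 1) += fs * dy; F(i, 2) += fs * dz;
      F(j, 0) -= fs * dx; F(j, 1) -= fs * dy; F(j, 2) -= fs * dz;
    }
  }
  return List::create(Named("energy") = U, Named("forces") = F);
}

// Truncated 12-6 Lennard-Jones among one site type (oxygens).
// [[Rcpp::export]]
List lj_cpp(NumericMatrix pos, NumericVector L, double eps, double sig,
            double rcut) {
  const int n = pos.nrow();
  const double rcut2 = rcut * rcut;
  double U = 0.0;
  NumericMatrix F(n, 3);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= L[0] * std::nearbyint(dx / L[0]);
      dy -= L[1] * std::nearbyint(dy / L[1]);
      dz -= L[2] * std::nearbyint(dz / L[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rcut2) continue;
      const double s2 = sig * sig / r2;
      const double s6 = s2 * s2 * s2;
      U += 4.0 * eps * s6 * (s6 - 1.0);
      const double fs = 24.0 * eps * s6 * (2.0 * s6 - 1.0) / r2;
      F(i, 0) += fs * dx; F(i, 1) += fs * dy; F(i, 2) += fs * dz;
      F(j, 0) -= fs * dx; F(j, 1) -= fs * dy; F(j, 2) -= fs * dz;
    }
  }
  return List::create(Named("energy") = U, Named("forces") = F);
}

// Intermolecular r^-12 repulsive walls between atom pairs (O-H and H-H);
// keeps bare charge sites from fusing in dynamics. spec[i] is 1 for O, 0
// for H; B_oh and B_hh are the wall strengths (eV Angstrom^12).
// [[Rcpp::export]]
List r12_walls_cpp(NumericMatrix pos, IntegerVector spec, IntegerVector mol,
                   NumericVector L, double B_oh, double B_hh, double rcut) {
  const int n = pos.nrow();
  const double rcut2 = rcut * rcut;
  double U = 0.0;
  NumericMatrix F(n, 3);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j]) continue;
      if (spec[i] == 1 && spec[j] == 1) continue;  // O-O handled by LJ
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= L[0] * std::nearbyint(dx / L[0]);
      dy -= L[1] * std::nearbyint(dy / L[1]);
      dz -= L[2] * std::nearbyint(dz / L[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rcut2) continue;
      const double B = (spec[i] != spec[j]) ? B_oh : B_hh;
      if (B <= 0.0) continue;
      const double inv2 = 1.0 / r2;
      const double inv12 = inv2 * inv2 * inv2 * inv2 * inv2 * inv2;
      U += B * inv12;
      const double fs = 12.0 * B * inv12 * inv2;
      F(i, 0) += fs * dx; F(i, 1) += fs * dy; F(i, 2) += fs * dz;
      F(j, 0) -= fs * dx; F(j, 1) -= fs * dy; F(j, 2) -= fs * dz;
    }
  }
  return List::create(Named("energy") = U, Named("forces") = F);
}
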