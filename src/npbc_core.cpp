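// Core numerical kernels: real spherical harmonics, Lennard-Jones + Coulomb
// pair interactions, the single-sphere conductor-like reaction field, and the
// rigid-body NVT/NPT simulation driver for nonperiodic (spherical) systems.
//
// Unit system: Angstrom, ps, amu, kJ/mol, elementary charge, Kelvin.
// 1 amu A^2 ps^-2 = 0.01 kJ/mol, so EN2MD converts kJ/mol forces into
// amu A ps^-2 accelerations after division by mass.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double K_E    = 1389.35458;       // kJ/mol * A / e^2
static const double K_B    = 0.008314462618;   // kJ/mol / K
static const double EN2MD  = 100.0;            // (kJ/mol) -> amu A^2/ps^2
static const double MD2EN  = 0.01;
static const double P_BAR  = 16605.390671738;  // bar per kJ/mol/A^3
static const double FOURPI = 12.566370614359172;

// ---------------------------------------------------------------------------
// Real orthonormal spherical harmonics, flat index l*(l+1)+m, m = -l..l.
// Pole-safe evaluation: Q_lm = normalized associated Legendre / sin^m(theta)
// via stable l-recurrences, combined with (cm, sm) = Re/Im of (x+iy)^m.
// ---------------------------------------------------------------------------
static void sph_all(int lmax, double x, double y, double z, double* Y) {
  const int nq = (lmax + 1) * (lmax + 2) / 2;
  std::vector<double> Q(nq);
  auto qi = [](int l, int m) { return l * (l + 1) / 2 + m; };
  Q[0] = 0.28209479177387814; // 1/sqrt(4 pi)
  for (int m = 1; m <= lmax; ++m)
    Q[qi(m, m)] = Q[qi(m - 1, m - 1)] * std::sqrt((2.0 * m + 1.0) / (2.0 * m));
  for (int m = 0; m < lmax; ++m)
    Q[qi(m + 1, m)] = std::sqrt(2.0 * m + 3.0) * z * Q[qi(m, m)];
  for (int m = 0; m <= lmax; ++m)
    for (int l = m + 2; l <= lmax; ++l) {
      double a = std::sqrt((4.0 * l * l - 1.0) / ((double)l * l - (double)m * m));
      double b = std::sqrt((((l - 1.0) * (l - 1.0) - (double)m * m)) /
                           (4.0 * (l - 1.0) * (l - 1.0) - 1.0));
      Q[qi(l, m)] = a * (z * Q[qi(l - 1, m)] - b * Q[qi(l - 2, m)]);
    }
  std::vector<double> cm(lmax + 1), sm(lmax + 1);
  cm[0] = 1.0; sm[0] = 0.0;
  for (int m = 1; m <= lmax; ++m) {
    cm[m] = cm[m - 1] * x - sm[m - 1] * y;
    sm[m] = sm[m - 1] * x + cm[m - 1] * y;
  }
  const double s2 = std::sqrt(2.0);
  for (int l = 0; l <= lmax; ++l) {
    Y[l * (l + 1)] = Q[qi(l, 0)];
    for (int m = 1; m <= l; ++m) {
      Y[l * (l + 1) + m] = s2 * Q[qi(l, m)] * cm[m];
      Y[l * (l + 1) - m] = s2 * Q[qi(l, m)] * sm[m];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sph_harm(int lmax, NumericMatrix dirs) {
  int n = dirs.nrow(), nb = (lmax + 1) * (lmax + 1);
  NumericMatrix out(n, nb);
  std::vector<double> Y(nb);
  for (int i = 0; i < n; ++i) {
    sph_all(lmax, dirs(i, 0), dirs(i, 1), dirs(i, 2), Y.data());
    for (int j = 0; j < nb; ++j) out(i, j) = Y[j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise Lennard-Jones (12-6, Lorentz-Berthelot) + Coulomb with
// intramolecular exclusion.  Virial is accumulated in the origin-independent
// molecular (centre-of-mass separation) form.
// ---------------------------------------------------------------------------
struct PairOut { double e_lj, e_coul, virial; };

static PairOut pair_forces_core(int nat, const double* x, const double* q,
                                const double* sig, const double* eps,
                                const int* mol, int nmol, const double* com,
                                double* f, bool do_lj, bool do_coul) {
  PairOut out{0.0, 0.0, 0.0};
  for (int i = 0; i < nat; ++i) {
    const double xi = x[i], yi = x[i + nat], zi = x[i + 2 * nat];
    const int mi = mol[i];
    for (int j = i + 1; j < nat; ++j) {
      if (mol[j] == mi) continue;
      double dx = xi - x[j], dy = yi - x[j + nat], dz = zi - x[j + 2 * nat];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12)
        stop("overlapping atoms %d and %d (r < 1e-6 A)", i + 1, j + 1);
      double fr = 0.0; // dE/dr / r  (so f_i = -fr * r_ij ... sign below)
      if (do_lj && eps[i] > 0.0 && eps[j] > 0.0) {
        double sij = 0.5 * (sig[i] + sig[j]);
        double eij = std::sqrt(eps[i] * eps[j]);
        double sr2 = sij * sij / r2;
        double sr6 = sr2 * sr2 * sr2;
        out.e_lj += 4.0 * eij * (sr6 * sr6 - sr6);
        fr += 24.0 * eij * (2.0 * sr6 * sr6 - sr6) / r2; // = |F|/r outward
      }
      if (do_coul && (q[i] != 0.0) && (q[j] != 0.0)) {
        double r = std::sqrt(r2);
        double ec = K_E * q[i] * q[j] / r;
        out.e_coul += ec;
        fr += ec / r2;
      }
      if (fr != 0.0) {
        double fx = fr * dx, fy = fr * dy, fz = fr * dz;
        f[i] += fx; f[i + nat] += fy; f[i + 2 * nat] += fz;
        f[j] -= fx; f[j + nat] -= fy; f[j + 2 * nat] -= fz;
        const int mj = mol[j];
        double cdx = com[mi] - com[mj];
        double cdy = com[mi + nmol] - com[mj + nmol];
        double cdz = com[mi + 2 * nmol] - com[mj + 2 * nmol];
        out.virial += cdx * fx + cdy * fy + cdz * fz;
      }
    }
  }
  return out;
}

static void mol_coms(int nat, const double* x, const double* mass,
                     const int* mol, int nmol, double* com, double* molmass) {
  for (int m = 0; m < 3 * nmol; ++m) com[m] = 0.0;
  for (int m = 0; m < nmol; ++m) molmass[m] = 0.0;
  for (int i = 0; i < nat; ++i) {
    int m = mol[i];
    molmass[m] += mass[i];
    com[m] += mass[i] * x[i];
    com[m + nmol] += mass[i] * x[i + nat];
    com[m + 2 * nmol] += mass[i] * x[i + 2 * nat];
  }
  for (int m = 0; m < nmol; ++m) {
    com[m] /= molmass[m];
    com[m + nmol] /= molmass[m];
    com[m + 2 * nmol] /= molmass[m];
  }
}

// [[Rcpp::export]]
List cpp_pair_forces(NumericMatrix x, NumericVector q, NumericVector sig,
                     NumericVector eps, IntegerVector mol, NumericVector mass,
                     bool do_lj = true, bool do_coul = true) {
  int nat = x.nrow();
  int nmol = 0;
  for (int i = 0; i < nat; ++i) nmol = std::max(nmol, mol[i] + 1);
  std::vector<double> com(3 * nmol), mm(nmol);
  mol_coms(nat, x.begin(), mass.begin(), mol.begin(), nmol, com.data(), mm.data());
  NumericMatrix f(nat, 3);
  PairOut po = pair_forces_core(nat, x.begin(), q.begin(), sig.begin(),
                                eps.begin(), mol.begin(), nmol, com.data(),
                                f.begin(), do_lj, do_coul);
  return List::create(_["energy"] = po.e_lj + po.e_coul,
                      _["e_lj"] = po.e_lj, _["e_coul"] = po.e_coul,
                      _["forces"] = f, _["virial"] = po.virial);
}

// ---------------------------------------------------------------------------
// Single-sphere conductor-like reaction field.
// phi_lm  = 4*pi * sum_n w_n Phi(R s_n) Y_lm(s_n)
// sigma_lm = -f(eps) (2l+1)/(4 pi k_e R) phi_lm      (diagonal COSMO solve)
// node charges Q_n = 4*pi w_n R^2 sum sigma_lm Y_lm(s_n)
// E = 1/2 sum_n Q_n Phi(R s_n);   F_k = q_k * field of the Q_n at r_k
// dE/dR = E/R + sum_n Q_n (s_n . grad Phi)(R s_n);  dE/dV = dE/dR / (4 pi R^2)
// ---------------------------------------------------------------------------
struct RFOut { double energy, dEdV; };

static RFOut rf_core(int nat, const double* x, const double* q, double Rcav,
                     const double* cen, int ng, const double* sx,
                     const double* sw, const double* Ynod, int nb, double feps,
                     double* f, double* phi_lm_out, double* sig_lm_out,
                     bool want_forces) {
  std::vector<double> phin(ng), gsn(ng);
  // potential and radial field-gradient projection at the quadrature nodes
  for (int n = 0; n < ng; ++n) {
    double px = cen[0] + Rcav * sx[n];
    double py = cen[1] + Rcav * sx[n + ng];
    double pz = cen[2] + Rcav * sx[n + 2 * ng];
    double p = 0.0, g = 0.0;
    for (int k = 0; k < nat; ++k) {
      if (q[k] == 0.0) continue;
      double dx = px - x[k], dy = py - x[k + nat], dz = pz - x[k + 2 * nat];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 2.5e-3) r2 = 2.5e-3; // clamp 0.05 A: guards transient wall crossings
      double r = std::sqrt(r2);
      p += q[k] / r;
      // s_n . grad Phi = -k_e q (d . s_n) / r^3
      double ds = dx * sx[n] + dy * sx[n + ng] + dz * sx[n + 2 * ng];
      g -= q[k] * ds / (r2 * r);
    }
    phin[n] = K_E * p;
    gsn[n] = K_E * g;
  }
  std::vector<double> phi_lm(nb, 0.0), sig_lm(nb, 0.0);
  for (int j = 0; j < nb; ++j) {
    double a = 0.0;
    for (int n = 0; n < ng; ++n) a += sw[n] * phin[n] * Ynod[n + j * ng];
    phi_lm[j] = FOURPI * a;
  }
  int l = 0, nextl = 1;
  for (int j = 0; j < nb; ++j) {
    if (j >= nextl * nextl) { l = nextl; nextl++; }
    sig_lm[j] = -feps * (2.0 * l + 1.0) / (FOURPI * K_E * Rcav) * phi_lm[j];
  }
  std::vector<double> Qn(ng);
  double E = 0.0, dEdR = 0.0;
  for (int n = 0; n < ng; ++n) {
    double s = 0.0;
    for (int j = 0; j < nb; ++j) s += sig_lm[j] * Ynod[n + j * ng];
    Qn[n] = FOURPI * sw[n] * Rcav * Rcav * s;
    E += 0.5 * Qn[n] * phin[n];
    dEdR += Qn[n] * gsn[n];
  }
  dEdR += E / Rcav;
  if (want_forces) {
    for (int n = 0; n < ng; ++n) {
      double px = cen[0] + Rcav * sx[n];
      double py = cen[1] + Rcav * sx[n + ng];
      double pz = cen[2] + Rcav * sx[n + 2 * ng];
      for (int k = 0; k < nat; ++k) {
        if (q[k] == 0.0) continue;
        double dx = x[k] - px, dy = x[k + nat] - py, dz = x[k + 2 * nat] - pz;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < 2.5e-3) r2 = 2.5e-3;
        double c = K_E * q[k] * Qn[n] / (r2 * std::sqrt(r2));
        f[k] += c * dx; f[k + nat] += c * dy; f[k + 2 * nat] += c * dz;
      }
    }
  }
  if (phi_lm_out) for (int j = 0; j < nb; ++j) phi_lm_out[j] = phi_lm[j];
  if (sig_lm_out) for (int j = 0; j < nb; ++j) sig_lm_out[j] = sig_lm[j];
  RFOut out{E, dEdR / (FOURPI * Rcav * Rcav)};
  return out;
}

// [[Rcpp::export]]
List cpp_reaction_field(NumericMatrix x, NumericVector q, double Rcav,
                        NumericVector center, NumericMatrix leb_xyz,
                        NumericVector leb_w, int lmax, double feps = 1.0,
                        bool want_forces = true) {
  int nat = x.nrow(), ng = leb_xyz.nrow(), nb = (lmax + 1) * (lmax + 1);
  NumericMatrix Y = cpp_sph_harm(lmax, leb_xyz);
  NumericMatrix f(nat, 3);
  NumericVector phi_lm(nb), sig_lm(nb);
  RFOut out = rf_core(nat, x.begin(), q.begin(), Rcav, center.begin(), ng,
                      leb_xyz.begin(), leb_w.begin(), Y.begin(), nb, feps,
                      f.begin(), phi_lm.begin(), sig_lm.begin(), want_forces);
  return List::create(_["energy"] = out.energy, _["forces"] = f,
                      _["dEdV"] = out.dEdV, _["phi_lm"] = phi_lm,
                      _["sigma_lm"] = sig_lm);
}

// ---------------------------------------------------------------------------
// Spectral ("quasi-analytical") reaction field.
// The boundary potential is projected on real solid harmonics
// S_lm(r) = r^l Y_lm(r_hat) analytically:
//   phi_lm = k_e sum_k q_k 4 pi/(2l+1) S_lm(r_k) / R^(l+1)
// giving E = -f/(8 pi k_e) sum (2l+1) phi_lm^2 and the smooth force
//   F_k = f q_k sum_lm phi_lm grad S_lm(r_k) / R^(l+1),
// which is the exact gradient of E (no quadrature-node singularities, so
// molecules may approach the boundary during dynamics).  Gradients of solid
// harmonics are expanded on the degree-(l-1) basis with coefficient matrices
// G built once by exact polynomial differentiation (Fornberg weights) and
// quadrature projection.
// ---------------------------------------------------------------------------

static void solid_all(int lmax, double x, double y, double z, double* S) {
  double r2 = x * x + y * y + z * z;
  double r = std::sqrt(r2);
  int nb = (lmax + 1) * (lmax + 1);
  if (r < 1e-14) {
    for (int j = 0; j < nb; ++j) S[j] = 0.0;
    S[0] = 0.28209479177387814;
    return;
  }
  sph_all(lmax, x / r, y / r, z / r, S);
  double rl = 1.0;
  for (int l = 1; l <= lmax; ++l) {
    rl *= r;
    for (int m = -l; m <= l; ++m) S[l * (l + 1) + m] *= rl;
  }
}

// Fornberg finite-difference weights for the first derivative at 0 on the
// symmetric grid {-M..M}*h; exact for polynomials of degree <= 2M.
static std::vector<double> fornberg_d1(int M, double h) {
  int n = 2 * M + 1;
  std::vector<double> xg(n);
  for (int i = 0; i < n; ++i) xg[i] = (i - M) * h;
  // Fornberg 1988 recursion, m = 0..1
  std::vector<double> c(n * 2, 0.0);
  double c1 = 1.0, c4 = xg[0];
  c[0] = 1.0;
  for (int i = 1; i < n; ++i) {
    double c2 = 1.0, c5 = c4;
    c4 = xg[i];
    for (int j = 0; j < i; ++j) {
      double c3 = xg[i] - xg[j];
      c2 *= c3;
      if (j == i - 1) {
        c[i * 2 + 1] = c1 * (c[(i - 1) * 2] - c5 * c[(i - 1) * 2 + 1]) / c2;
        c[i * 2] = -c1 * c5 * c[(i - 1) * 2] / c2;
      }
      c[j * 2 + 1] = (c4 * c[j * 2 + 1] - c[j * 2]) / c3;
      c[j * 2] = c4 * c[j * 2] / c3;
    }
    c1 = c2;
  }
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) w[i] = c[i * 2 + 1];
  return w;
}

// gradient expansion matrices: grad_a S_lm = sum_m' G[l][a](m, m') S_(l-1)m'
// G[l][a] stored row-major (2l+1) x (2l-1), l = 1..lmax
static std::vector<std::vector<std::vector<double>>> solid_grad_mats(
    int lmax, const NumericMatrix& leb_xyz, const NumericVector& leb_w) {
  int ng = leb_xyz.nrow();
  std::vector<std::vector<std::vector<double>>> G(lmax + 1);
  int nbfull = (lmax + 1) * (lmax + 1);
  std::vector<double> Sbuf(nbfull), Ynm((lmax + 1) * (lmax + 1));
  for (int l = 1; l <= lmax; ++l) {
    int M = l / 2 + 1;       // 2M >= l ensures exact differentiation
    double h = 0.1;
    std::vector<double> w = fornberg_d1(M, h);
    int nst = 2 * M + 1;
    G[l].assign(3, std::vector<double>((2 * l + 1) * (2 * l - 1), 0.0));
    for (int n = 0; n < ng; ++n) {
      double p[3] = {leb_xyz(n, 0), leb_xyz(n, 1), leb_xyz(n, 2)};
      sph_all(lmax, p[0], p[1], p[2], Ynm.data());
      for (int a = 0; a < 3; ++a) {
        // dS_lm/da at p, exact for the degree-l polynomials
        std::vector<double> dS(2 * l + 1, 0.0);
        for (int s = 0; s < nst; ++s) {
          if (w[s] == 0.0) continue;
          double pp[3] = {p[0], p[1], p[2]};
          pp[a] += (s - M) * h;
          solid_all(l, pp[0], pp[1], pp[2], Sbuf.data());
          for (int m = -l; m <= l; ++m)
            dS[m + l] += w[s] * Sbuf[l * (l + 1) + m];
        }
        // project on Y_(l-1)m' over the sphere (dS is degree l-1, exact)
        for (int m = -l; m <= l; ++m)
          for (int mp = -(l - 1); mp <= l - 1; ++mp)
            G[l][a][(m + l) * (2 * l - 1) + (mp + l - 1)] +=
              FOURPI * leb_w[n] * dS[m + l] * Ynm[(l - 1) * l + mp];
      }
    }
  }
  return G;
}

struct RFAnalytic {
  int lmax, nb;
  double feps;
  std::vector<std::vector<std::vector<double>>> G;
  std::vector<double> phi, psi[3], Sbuf;
  void init(int lmax_, double feps_, const NumericMatrix& leb_xyz,
            const NumericVector& leb_w) {
    lmax = lmax_; feps = feps_;
    nb = (lmax + 1) * (lmax + 1);
    G = solid_grad_mats(lmax, leb_xyz, leb_w);
    phi.assign(nb, 0.0);
    for (int a = 0; a < 3; ++a) psi[a].assign(nb, 0.0);
    Sbuf.assign(nb, 0.0);
  }
  // returns energy; adds forces into f; sets dEdV
  double compute(int nat, const double* x, const double* q, double Rcav,
                 double* f, double* dEdV) {
    std::fill(phi.begin(), phi.end(), 0.0);
    std::vector<double> Rpow(lmax + 2);
    Rpow[0] = 1.0 / Rcav;
    for (int l = 1; l <= lmax + 1; ++l) Rpow[l] = Rpow[l - 1] / Rcav;
    // atoms transiently beyond the wall (before the rough wall re-injects
    // their molecule) are evaluated at a radially clamped position: the
    // interior expansion is only valid inside the cavity, and (r/R)^l growth
    // outside would eject them
    const double rclamp = 0.97 * Rcav;
    std::vector<double> cl(nat, 1.0);
    for (int k = 0; k < nat; ++k) {
      double r = std::sqrt(x[k] * x[k] + x[k + nat] * x[k + nat] +
                           x[k + 2 * nat] * x[k + 2 * nat]);
      if (r > rclamp) cl[k] = rclamp / r;
    }
    for (int k = 0; k < nat; ++k) {
      if (q[k] == 0.0) continue;
      solid_all(lmax, cl[k] * x[k], cl[k] * x[k + nat],
                cl[k] * x[k + 2 * nat], Sbuf.data());
      for (int l = 0; l <= lmax; ++l) {
        double c = K_E * q[k] * FOURPI / (2.0 * l + 1.0) * Rpow[l];
        for (int m = -l; m <= l; ++m)
          phi[l * (l + 1) + m] += c * Sbuf[l * (l + 1) + m];
      }
    }
    double E = 0.0, dEdR = 0.0;
    const double pref = -feps / (2.0 * FOURPI * K_E);
    for (int l = 0; l <= lmax; ++l) {
      double s = 0.0;
      for (int m = -l; m <= l; ++m) {
        double v = phi[l * (l + 1) + m];
        s += v * v;
      }
      double El = pref * (2.0 * l + 1.0) * s * Rcav;
      E += El;
      dEdR += -(2.0 * l + 1.0) * El / Rcav;
    }
    *dEdV = dEdR / (FOURPI * Rcav * Rcav);
    if (f) {
      for (int a = 0; a < 3; ++a) std::fill(psi[a].begin(), psi[a].end(), 0.0);
      for (int l = 1; l <= lmax; ++l)
        for (int a = 0; a < 3; ++a)
          for (int m = -l; m <= l; ++m) {
            // F_k = f q_k sum_lm phi_lm R^(-l) grad S_lm(r_k)
            double pv = phi[l * (l + 1) + m] * Rpow[l - 1];
            if (pv == 0.0) continue;
            const double* row = &G[l][a][(m + l) * (2 * l - 1)];
            for (int mp = -(l - 1); mp <= l - 1; ++mp)
              psi[a][(l - 1) * l + mp] += pv * row[mp + l - 1];
          }
      int nbm = lmax * lmax; // basis size up to lmax-1
      for (int k = 0; k < nat; ++k) {
        if (q[k] == 0.0) continue;
        solid_all(lmax - 1, cl[k] * x[k], cl[k] * x[k + nat],
                  cl[k] * x[k + 2 * nat], Sbuf.data());
        double fk[3];
        for (int a = 0; a < 3; ++a) {
          double acc = 0.0;
          for (int j = 0; j < nbm; ++j) acc += psi[a][j] * Sbuf[j];
          fk[a] = feps * q[k] * acc;
        }
        if (cl[k] < 1.0) {
          // clamped atom: transfer only the tangential component, scaled by
          // the clamp factor (chain rule of the radial projection)
          double r2 = x[k] * x[k] + x[k + nat] * x[k + nat] +
                      x[k + 2 * nat] * x[k + 2 * nat];
          double dot = (fk[0] * x[k] + fk[1] * x[k + nat] +
                        fk[2] * x[k + 2 * nat]) / r2;
          fk[0] = cl[k] * (fk[0] - dot * x[k]);
          fk[1] = cl[k] * (fk[1] - dot * x[k + nat]);
          fk[2] = cl[k] * (fk[2] - dot * x[k + 2 * nat]);
        }
        f[k] += fk[0]; f[k + nat] += fk[1]; f[k + 2 * nat] += fk[2];
      }
    }
    return E;
  }
};

// [[Rcpp::export]]
List cpp_reaction_field_spectral(NumericMatrix x, NumericVector q, double Rcav,
                                 NumericVector center, int lmax,
                                 NumericMatrix leb_xyz, NumericVector leb_w,
                                 double feps = 1.0) {
  int nat = x.nrow();
  NumericMatrix xc(nat, 3);
  for (int i = 0; i < nat; ++i)
    for (int a = 0; a < 3; ++a) xc(i, a) = x(i, a) - center[a];
  RFAnalytic rf;
  rf.init(lmax, feps, leb_xyz, leb_w);
  NumericMatrix f(nat, 3);
  double dEdV = 0.0;
  double E = rf.compute(nat, xc.begin(), q.begin(), Rcav, f.begin(), &dEdV);
  NumericVector phi(rf.nb);
  for (int j = 0; j < rf.nb; ++j) phi[j] = rf.phi[j];
  return List::create(_["energy"] = E, _["forces"] = f, _["dEdV"] = dEdV,
                      _["phi_lm"] = phi);
}

// ---------------------------------------------------------------------------
// Quaternion helpers (scalar-first, body->lab rotation).
// ---------------------------------------------------------------------------
static inline void quat_rot(const double* q, double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

static inline void quat_dot(const double* q, const double* Llab,
                            const double* I, double* qd) {
  double R[3][3];
  quat_rot(q, R);
  // body-frame angular momentum = R^T L, omega = I^-1 Lbody
  double lb[3], om[3];
  for (int a = 0; a < 3; ++a)
    lb[a] = R[0][a] * Llab[0] + R[1][a] * Llab[1] + R[2][a] * Llab[2];
  for (int a = 0; a < 3; ++a) om[a] = (I[a] > 0.0) ? lb[a] / I[a] : 0.0;
  // qdot = 1/2 q * (0, omega_body)
  qd[0] = 0.5 * (-q[1] * om[0] - q[2] * om[1] - q[3] * om[2]);
  qd[1] = 0.5 * ( q[0] * om[0] - q[3] * om[1] + q[2] * om[2]);
  qd[2] = 0.5 * ( q[3] * om[0] + q[0] * om[1] - q[1] * om[2]);
  qd[3] = 0.5 * (-q[2] * om[0] + q[1] * om[1] + q[0] * om[2]);
}

static inline void quat_norm(double* q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int a = 0; a < 4; ++a) q[a] /= n;
}

// Implicit-midpoint quaternion drift with self-consistent iteration on the
// quaternion time derivative (converged to eps), angular momentum held fixed.
static int quat_drift_once(double* q, const double* Llab, const double* I,
                           double dt, double eps, int maxit) {
  double q0[4] = {q[0], q[1], q[2], q[3]};
  double qd[4], qn[4], qmid[4];
  quat_dot(q0, Llab, I, qd);
  for (int a = 0; a < 4; ++a) qn[a] = q0[a] + dt * qd[a];
  for (int it = 0; it < maxit; ++it) {
    for (int a = 0; a < 4; ++a) qmid[a] = 0.5 * (q0[a] + qn[a]);
    quat_norm(qmid);
    quat_dot(qmid, Llab, I, qd);
    double delta = 0.0;
    for (int a = 0; a < 4; ++a) {
      double v = q0[a] + dt * qd[a];
      delta = std::max(delta, std::fabs(v - qn[a]));
      qn[a] = v;
    }
    if (delta < eps) {
      quat_norm(qn);
      for (int a = 0; a < 4; ++a) q[a] = qn[a];
      return it + 1;
    }
  }
  return -1;
}

// Adaptive substepping keeps dt*omega small so the fixed-point iteration
// contracts even for molecules spun up by a collision or a wall reset.
static int quat_drift(double* q, const double* Llab, const double* I,
                      double dt, double eps, int maxit) {
  double R[3][3];
  quat_rot(q, R);
  double om2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    double lb = R[0][a] * Llab[0] + R[1][a] * Llab[1] + R[2][a] * Llab[2];
    if (I[a] > 0.0) { double o = lb / I[a]; om2 += o * o; }
  }
  int nsub = (int)std::ceil(dt * std::sqrt(om2) / 0.1);
  if (nsub < 1) nsub = 1;
  if (nsub > 10000) return -1;
  for (int s = 0; s < nsub; ++s)
    if (quat_drift_once(q, Llab, I, dt / nsub, eps, maxit) < 0) return -1;
  return nsub;
}

static double rot_kinetic_md(const double* q, const double* Llab,
                             const double* I) {
  double R[3][3];
  quat_rot(q, R);
  double k = 0.0;
  for (int a = 0; a < 3; ++a) {
    double lb = R[0][a] * Llab[0] + R[1][a] * Llab[1] + R[2][a] * Llab[2];
    if (I[a] > 0.0) k += 0.5 * lb * lb / I[a];
  }
  return k;
}

// Torque-free rigid-rotor propagation (used by integrator-conservation tests).
// [[Rcpp::export]]
List cpp_free_rotor(NumericVector inertia, NumericVector q0, NumericVector L0,
                    double dt, int nsteps, double eps = 1e-9,
                    int sample_stride = 1) {
  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  double L[3] = {L0[0], L0[1], L0[2]};
  double I[3] = {inertia[0], inertia[1], inertia[2]};
  int ns = nsteps / sample_stride + 1;
  NumericVector ke(ns);
  NumericMatrix qs(ns, 4);
  int row = 0;
  ke[0] = rot_kinetic_md(q, L, I) * MD2EN;
  for (int a = 0; a < 4; ++a) qs(0, a) = q[a];
  row = 1;
  for (int s = 1; s <= nsteps; ++s) {
    if (quat_drift(q, L, I, dt, eps, 200) < 0)
      stop("quaternion iteration failed to converge at step %d", s);
    if (s % sample_stride == 0 && row < ns) {
      ke[row] = rot_kinetic_md(q, L, I) * MD2EN;
      for (int a = 0; a < 4; ++a) qs(row, a) = q[a];
      ++row;
    }
  }
  return List::create(_["kinetic"] = ke, _["quaternions"] = qs);
}

// ---------------------------------------------------------------------------
// Rigid-body NVT/NPT driver.
// Per-step sequence: half-kick -> drift (COM + quaternion) -> forces ->
// half-kick -> rough wall -> thermostat -> (NPT) pressure + weak-coupling
// scaling of molecular COMs and cavity radius.
// ---------------------------------------------------------------------------

struct MFSpec {
  bool on = false;
  std::vector<double> coef; // polynomial on boundary distance
  double cutoff = 0.0;
  bool tab_on = false;
  std::vector<double> tabv; // tabulated correction on |com| shells
  double tab_dr = 0.0;
};

// polynomial value and derivative via Horner
static inline void polyval2(const std::vector<double>& a, double x, double* v,
                            double* d) {
  double p = 0.0, dp = 0.0;
  for (int i = (int)a.size() - 1; i >= 0; --i) {
    dp = dp * x + p;
    p = p * x + a[i];
  }
  *v = p; *d = dp;
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix bodyref, IntegerVector mol, NumericVector amass,
                NumericVector q, NumericVector sig, NumericVector eps,
                NumericMatrix inertia, NumericVector molmass,
                LogicalVector free_body,
                NumericMatrix com0, NumericMatrix v0, NumericMatrix quat0,
                NumericMatrix L0, double R0,
                double dt, int nsteps, double temperature, double tau_t,
                bool npt, double p0, double tau_p, double beta_p,
                double alpha_box,
                bool rf_on, int rf_lmax, NumericMatrix leb_xyz,
                NumericVector leb_w, double rf_feps, double rf_offset,
                bool rf_in_pressure,
                bool mf_on, NumericVector mf_coef, double mf_cutoff,
                bool tab_on, NumericVector tab_values,
                bool wall_on, bool do_lj, bool do_coul,
                int traj_stride, int log_stride, double t0 = 0.0,
                double quat_eps = 1e-9) {
  const int nat = bodyref.nrow();
  const int nmol = com0.nrow();
  const int nb = (rf_lmax + 1) * (rf_lmax + 1);
  const int ng = rf_on ? leb_xyz.nrow() : 0;

  std::vector<double> com(com0.begin(), com0.end());
  std::vector<double> vel(v0.begin(), v0.end());
  std::vector<double> qt(quat0.begin(), quat0.end()); // nmol x 4 col-major
  std::vector<double> L(L0.begin(), L0.end());
  std::vector<double> x(3 * nat), f(3 * nat);
  std::vector<double> Fm(3 * nmol), Tq(3 * nmol);
  std::vector<bool> rot(nmol);
  double Rcav = R0;

  MFSpec mf;
  mf.on = mf_on;
  if (mf_on) {
    mf.coef.assign(mf_coef.begin(), mf_coef.end());
    mf.cutoff = mf_cutoff;
  }
  mf.tab_on = tab_on;
  if (tab_on) {
    mf.tabv.assign(tab_values.begin(), tab_values.end());
    mf.tab_dr = R0 / (double)mf.tabv.size();
  }

  for (int m = 0; m < nmol; ++m)
    rot[m] = (inertia(m, 0) > 0.0 || inertia(m, 1) > 0.0 || inertia(m, 2) > 0.0);

  int ndf = 0, nfree = 0;
  for (int m = 0; m < nmol; ++m)
    if (free_body[m]) { ndf += rot[m] ? 6 : 3; ++nfree; }

  // spectral reaction field: gradient-expansion matrices built once (the
  // Lebedev grid enters only this projection)
  RFAnalytic rfa;
  if (rf_on) rfa.init(rf_lmax, rf_feps, leb_xyz, leb_w);

  auto rebuild_positions = [&](void) {
    for (int m = 0; m < nmol; ++m) {
      double R[3][3];
      double qq[4] = {qt[m], qt[m + nmol], qt[m + 2 * nmol], qt[m + 3 * nmol]};
      quat_rot(qq, R);
      for (int i = 0; i < nat; ++i) {
        if (mol[i] != m) continue;
        double bx = bodyref(i, 0), by = bodyref(i, 1), bz = bodyref(i, 2);
        x[i]           = com[m]            + R[0][0] * bx + R[0][1] * by + R[0][2] * bz;
        x[i + nat]     = com[m + nmol]     + R[1][0] * bx + R[1][1] * by + R[1][2] * bz;
        x[i + 2 * nat] = com[m + 2 * nmol] + R[2][0] * bx + R[2][1] * by + R[2][2] * bz;
      }
    }
  };

  double e_pair = 0.0, e_mf = 0.0, e_rf = 0.0, virial = 0.0, dEdV = 0.0;

  auto compute_forces = [&](void) {
    std::fill(f.begin(), f.end(), 0.0);
    e_pair = e_mf = e_rf = virial = dEdV = 0.0;
    if (do_lj || do_coul) {
      PairOut po = pair_forces_core(nat, x.data(), q.begin(), sig.begin(),
                                    eps.begin(), mol.begin(), nmol, com.data(),
                                    f.data(), do_lj, do_coul);
      e_pair = po.e_lj + po.e_coul;
      virial = po.virial;
    }
    if (mf.on || mf.tab_on) {
      for (int m = 0; m < nmol; ++m) {
        double cx = com[m], cy = com[m + nmol], cz = com[m + 2 * nmol];
        double s = std::sqrt(cx * cx + cy * cy + cz * cz);
        double fr = 0.0; // radial force (along +r_hat)
        if (mf.on) {
          double barg = Rcav - s;
          if (barg < 0.0) barg = 0.0;
          if (barg < mf.cutoff) {
            double v, d;
            polyval2(mf.coef, barg, &v, &d);
            e_mf += v;
            fr += d; // F = -dU/ds r_hat = +p'(R-s) r_hat
          }
        }
        if (mf.tab_on && mf.tab_dr > 0.0) {
          // piecewise-linear tabulated correction on |com|
          double u = s / mf.tab_dr - 0.5;
          int nsh = (int)mf.tabv.size();
          int i0 = (int)std::floor(u);
          double w1 = u - i0;
          int ia = std::min(std::max(i0, 0), nsh - 1);
          int ib = std::min(std::max(i0 + 1, 0), nsh - 1);
          e_mf += (1.0 - w1) * mf.tabv[ia] + w1 * mf.tabv[ib];
          double slope = (ia == ib) ? 0.0 : (mf.tabv[ib] - mf.tabv[ia]) / mf.tab_dr;
          fr -= slope;
        }
        if (fr != 0.0 && s > 1e-9) {
          double ux = cx / s, uy = cy / s, uz = cz / s;
          // distribute to atoms by mass fraction
          for (int i = 0; i < nat; ++i) {
            if (mol[i] != m) continue;
            double wfrac = amass[i] / molmass[m];
            f[i] += wfrac * fr * ux;
            f[i + nat] += wfrac * fr * uy;
            f[i + 2 * nat] += wfrac * fr * uz;
          }
          virial += fr * s; // com . F
        }
      }
    }
    if (rf_on) {
      double R_rf = Rcav + rf_offset;
      std::vector<double> frf(3 * nat, 0.0);
      e_rf = rfa.compute(nat, x.data(), q.begin(), R_rf, frf.data(), &dEdV);
      // dE/dV of the confining volume: dE/dR_rf / (4 pi R^2)
      dEdV *= (R_rf * R_rf) / (Rcav * Rcav);
      // the reaction-field forces are real forces on the atoms and belong in
      // the Clausius virial (molecular form); the explicit cavity-radius
      // derivative dEdV is the piece the virial cannot see.  Omitting the
      // force virial while keeping dEdV breaks the near-cancellation implied
      // by the Coulomb scaling of the reaction field and gives an absurd
      // equation of state.
      for (int m = 0; m < nmol; ++m) {
        double fx = 0.0, fy = 0.0, fz = 0.0;
        for (int i = 0; i < nat; ++i) {
          if (mol[i] != m) continue;
          fx += frf[i]; fy += frf[i + nat]; fz += frf[i + 2 * nat];
        }
        virial += com[m] * fx + com[m + nmol] * fy + com[m + 2 * nmol] * fz;
      }
      for (int i = 0; i < 3 * nat; ++i) f[i] += frf[i];
    }
    // per-body force and torque
    std::fill(Fm.begin(), Fm.end(), 0.0);
    std::fill(Tq.begin(), Tq.end(), 0.0);
    for (int i = 0; i < nat; ++i) {
      int m = mol[i];
      double fx = f[i], fy = f[i + nat], fz = f[i + 2 * nat];
      Fm[m] += fx; Fm[m + nmol] += fy; Fm[m + 2 * nmol] += fz;
      double rx = x[i] - com[m], ry = x[i + nat] - com[m + nmol],
             rz = x[i + 2 * nat] - com[m + 2 * nmol];
      Tq[m] += ry * fz - rz * fy;
      Tq[m + nmol] += rz * fx - rx * fz;
      Tq[m + 2 * nmol] += rx * fy - ry * fx;
    }
  };

  auto kinetic_md = [&](double* ktrans, double* krot) {
    double kt = 0.0, kr = 0.0;
    for (int m = 0; m < nmol; ++m) {
      if (!free_body[m]) continue;
      double vx = vel[m], vy = vel[m + nmol], vz = vel[m + 2 * nmol];
      kt += 0.5 * molmass[m] * (vx * vx + vy * vy + vz * vz);
      if (rot[m]) {
        double qq[4] = {qt[m], qt[m + nmol], qt[m + 2 * nmol], qt[m + 3 * nmol]};
        double ll[3] = {L[m], L[m + nmol], L[m + 2 * nmol]};
        double II[3] = {inertia(m, 0), inertia(m, 1), inertia(m, 2)};
        kr += rot_kinetic_md(qq, ll, II);
      }
    }
    *ktrans = kt; *krot = kr;
  };

  rebuild_positions();
  compute_forces();

  const int nframes = nsteps / traj_stride;
  NumericVector traj((R_xlen_t)3 * nat * nframes);
  NumericVector traj_R(nframes), traj_t(nframes);
  const int nlog = nsteps / log_stride;
  NumericMatrix log(nlog, 10);
  colnames(log) = CharacterVector::create("time", "T", "P", "E_pair", "E_mf",
                                          "E_rf", "E_kin", "R", "wall_events",
                                          "P_wall");
  int fidx = 0, lidx = 0;
  double wall_acc = 0.0;
  GetRNGstate();
  for (int step = 1; step <= nsteps; ++step) {
    // half kick
    for (int m = 0; m < nmol; ++m) {
      if (!free_body[m]) continue;
      double c = 0.5 * dt * EN2MD / molmass[m];
      vel[m] += c * Fm[m];
      vel[m + nmol] += c * Fm[m + nmol];
      vel[m + 2 * nmol] += c * Fm[m + 2 * nmol];
      if (rot[m]) {
        L[m] += 0.5 * dt * EN2MD * Tq[m];
        L[m + nmol] += 0.5 * dt * EN2MD * Tq[m + nmol];
        L[m + 2 * nmol] += 0.5 * dt * EN2MD * Tq[m + 2 * nmol];
      }
    }
    // drift
    for (int m = 0; m < nmol; ++m) {
      if (!free_body[m]) continue;
      com[m] += dt * vel[m];
      com[m + nmol] += dt * vel[m + nmol];
      com[m + 2 * nmol] += dt * vel[m + 2 * nmol];
      if (rot[m]) {
        double qq[4] = {qt[m], qt[m + nmol], qt[m + 2 * nmol], qt[m + 3 * nmol]};
        double ll[3] = {L[m], L[m + nmol], L[m + 2 * nmol]};
        double II[3] = {inertia(m, 0), inertia(m, 1), inertia(m, 2)};
        if (quat_drift(qq, ll, II, dt, quat_eps, 200) < 0) {
          PutRNGstate();
          stop("quaternion iteration did not converge (molecule %d, step %d)",
               m + 1, step);
        }
        qt[m] = qq[0]; qt[m + nmol] = qq[1];
        qt[m + 2 * nmol] = qq[2]; qt[m + 3 * nmol] = qq[3];
      }
    }
    rebuild_positions();
    compute_forces();
    // half kick
    for (int m = 0; m < nmol; ++m) {
      if (!free_body[m]) continue;
      double c = 0.5 * dt * EN2MD / molmass[m];
      vel[m] += c * Fm[m];
      vel[m + nmol] += c * Fm[m + nmol];
      vel[m + 2 * nmol] += c * Fm[m + 2 * nmol];
      if (rot[m]) {
        L[m] += 0.5 * dt * EN2MD * Tq[m];
        L[m + nmol] += 0.5 * dt * EN2MD * Tq[m + nmol];
        L[m + 2 * nmol] += 0.5 * dt * EN2MD * Tq[m + 2 * nmol];
      }
    }
    // rough wall
    int wall_events = 0;
    double wall_impulse = 0.0; // radial momentum handed to the wall (amu A/ps)
    if (wall_on) {
      for (int m = 0; m < nmol; ++m) {
        if (!free_body[m]) continue;
        double cx = com[m], cy = com[m + nmol], cz = com[m + 2 * nmol];
        double s2 = cx * cx + cy * cy + cz * cz;
        if (s2 <= Rcav * Rcav) continue;
        ++wall_events;
        double s = std::sqrt(s2);
        double ux, uy, uz, un;
        do {
          ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
          un = std::sqrt(ux * ux + uy * uy + uz * uz);
        } while (un < 1e-12);
        ux /= un; uy /= un; uz /= un;
        if (ux * cx + uy * cy + uz * cz > 0.0) { ux = -ux; uy = -uy; uz = -uz; }
        double vmean = std::sqrt(8.0 * K_B * temperature * EN2MD /
                                 (M_PI * molmass[m]));
        double rx = cx / s, ry = cy / s, rz = cz / s;
        double vr_old = vel[m] * rx + vel[m + nmol] * ry +
                        vel[m + 2 * nmol] * rz;
        vel[m] = vmean * ux; vel[m + nmol] = vmean * uy;
        vel[m + 2 * nmol] = vmean * uz;
        double vr_new = vel[m] * rx + vel[m + nmol] * ry +
                        vel[m + 2 * nmol] * rz;
        wall_impulse += molmass[m] * (vr_old - vr_new);
        if (rot[m]) {
          double wx, wy, wz, wn;
          do {
            wx = norm_rand(); wy = norm_rand(); wz = norm_rand();
            wn = std::sqrt(wx * wx + wy * wy + wz * wz);
          } while (wn < 1e-12);
          double itot = inertia(m, 0) + inertia(m, 1) + inertia(m, 2);
          double lmag = std::sqrt(itot * K_B * temperature * EN2MD);
          L[m] = lmag * wx / wn;
          L[m + nmol] = lmag * wy / wn;
          L[m + 2 * nmol] = lmag * wz / wn;
        }
        (void)s;
      }
    }
    // thermostat (stochastic velocity rescaling)
    double ktrans, krot;
    kinetic_md(&ktrans, &krot);
    if (tau_t > 0.0 && ndf > 0 && (ktrans + krot) > 0.0) {
      double K = ktrans + krot;
      double Kbar = 0.5 * ndf * K_B * temperature * EN2MD;
      double c = std::exp(-dt / tau_t);
      double r1 = norm_rand();
      double ssum = (ndf > 1) ? ::Rf_rchisq((double)(ndf - 1)) : 0.0;
      double a2 = c + (Kbar / (ndf * K)) * (1.0 - c) * (r1 * r1 + ssum) +
                  2.0 * r1 * std::sqrt(c * (1.0 - c) * Kbar / (ndf * K));
      double alpha = std::sqrt(std::max(a2, 0.0));
      for (int m = 0; m < nmol; ++m) {
        if (!free_body[m]) continue;
        vel[m] *= alpha; vel[m + nmol] *= alpha; vel[m + 2 * nmol] *= alpha;
        L[m] *= alpha; L[m + nmol] *= alpha; L[m + 2 * nmol] *= alpha;
      }
      ktrans *= a2; krot *= a2;
    }
    // instantaneous pressure (molecular virial, translational kinetic part)
    double V = FOURPI / 3.0 * Rcav * Rcav * Rcav;
    double P = (2.0 * ktrans * MD2EN + virial) / (3.0 * V);
    if (rf_on && rf_in_pressure) P -= dEdV;
    double P_bar_inst = P * P_BAR;
    // barostat
    if (npt && tau_p > 0.0) {
      double mu3 = 1.0 - alpha_box * beta_p * (dt / tau_p) * (p0 - P_bar_inst);
      double mu = std::cbrt(mu3);
      if (mu < 0.95) mu = 0.95;
      if (mu > 1.05) mu = 1.05;
      for (int m = 0; m < 3 * nmol; ++m) com[m] *= mu;
      Rcav *= mu;
      rebuild_positions();
    }
    // sanity
    if (!std::isfinite(com[0]) || !std::isfinite(P_bar_inst)) {
      PutRNGstate();
      stop("non-finite state at step %d", step);
    }
    wall_acc += wall_impulse;
    // logging
    if (step % log_stride == 0 && lidx < nlog) {
      double Ttot = (ndf > 0)
        ? 2.0 * (ktrans + krot) * MD2EN / (ndf * K_B) : 0.0;
      log(lidx, 0) = t0 + step * dt;
      log(lidx, 1) = Ttot;
      log(lidx, 2) = P_bar_inst;
      log(lidx, 3) = e_pair;
      log(lidx, 4) = e_mf;
      log(lidx, 5) = e_rf;
      log(lidx, 6) = (ktrans + krot) * MD2EN;
      log(lidx, 7) = Rcav;
      log(lidx, 8) = wall_events;
      // mean mechanical pressure on the wall over the log window, in bar
      log(lidx, 9) = wall_acc / (log_stride * dt) /
        (FOURPI * Rcav * Rcav) * MD2EN * P_BAR;
      wall_acc = 0.0;
      ++lidx;
    }
    if (step % traj_stride == 0 && fidx < nframes) {
      for (int i = 0; i < nat; ++i) {
        traj[(R_xlen_t)fidx * 3 * nat + i] = x[i];
        traj[(R_xlen_t)fidx * 3 * nat + nat + i] = x[i + nat];
        traj[(R_xlen_t)fidx * 3 * nat + 2 * nat + i] = x[i + 2 * nat];
      }
      traj_R[fidx] = Rcav;
      traj_t[fidx] = t0 + step * dt;
      ++fidx;
    }
  }
  PutRNGstate();
  traj.attr("dim") = IntegerVector::create(nat, 3, nframes);
  NumericMatrix com_out(nmol, 3), v_out(nmol, 3), q_out(nmol, 4), L_out(nmol, 3);
  for (int m = 0; m < nmol; ++m)
    for (int a = 0; a < 3; ++a) {
      com_out(m, a) = com[m + a * nmol];
      v_out(m, a) = vel[m + a * nmol];
      L_out(m, a) = L[m + a * nmol];
    }
  for (int m = 0; m < nmol; ++m)
    for (int a = 0; a < 4; ++a) q_out(m, a) = qt[m + a * nmol];
  NumericMatrix x_out(nat, 3);
  for (int i = 0; i < nat; ++i)
    for (int a = 0; a < 3; ++a) x_out(i, a) = x[i + a * nat];
  return List::create(_["traj"] = traj, _["traj_R"] = traj_R,
                      _["traj_time"] = traj_t, _["log"] = log,
                      _["com"] = com_out, _["vel"] = v_out,
                      _["quat"] = q_out, _["angmom"] = L_out,
                      _["positions"] = x_out, _["radius"] = Rcav,
                      _["ndf"] = ndf);
}
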