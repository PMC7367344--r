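// Pair forces (Mie / continuous square-well), cell-list neighbour search and
// a BAOAB Langevin integrator for a binary mixture in a cubic periodic box.
// Lengths in r_a (= sigma_aa), energies in epsilon, masses in m_a; the time
// unit t_s = sqrt(m_a r_a^2 / epsilon) is then 1.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct PotPars {
  int family;            // 0 = mie, 1 = csw
  double eps, n, m;
  double sigma[3];       // pair-type aa, ab, bb (contact distance)
  double rsw;            // csw well width (units of contact distance)
  double prefac;         // mie normalisation C
  double rc;             // global cutoff (absolute length)
  double shift[3];       // energy shift so U(rc) = 0 per pair type
  int ni, mi;            // integer exponents (-1 when not integral)
};

static inline double ipow(double x, int e) {
  double r = 1.0;
  while (e > 0) {
    if (e & 1) r *= x;
    x *= x;
    e >>= 1;
  }
  return r;
}

static inline double pow_e(double x, double e, int ei) {
  return ei >= 0 ? ipow(x, ei) : std::pow(x, e);
}

static inline double pot_u(const PotPars& p, int type, double r) {
  if (r >= p.rc) return 0.0;
  const double s = p.sigma[type];
  if (p.family == 0) {
    double x = s / r;
    double xm = pow_e(x, p.m, p.mi);
    double xn = pow_e(x, p.n, p.ni);
    return p.prefac * p.eps * (xn - xm) - p.shift[type];
  }
  double rr = r / s;  // csw written in units of the contact distance
  double x = p.m * (rr - 1.0) * (rr - p.rsw);
  return 0.5 * p.eps * (pow_e(1.0 / rr, p.n, p.ni) + std::tanh(0.5 * x) -
                        1.0) -
         p.shift[type];
}

// radial force magnitude f = -dU/dr (positive = repulsive)
static inline double pot_f(const PotPars& p, int type, double r) {
  if (r >= p.rc) return 0.0;
  const double s = p.sigma[type];
  if (p.family == 0) {
    double x = s / r;
    double xm = pow_e(x, p.m, p.mi);
    double xn = pow_e(x, p.n, p.ni);
    return p.prefac * p.eps * (p.n * xn - p.m * xm) / r;
  }
  double rr = r / s;
  double x = p.m * (rr - 1.0) * (rr - p.rsw);
  double ch = std::cosh(0.5 * x);
  double sech2 = (ch > 1e150) ? 0.0 : 1.0 / (ch * ch);
  double dx = p.m * (2.0 * rr - 1.0 - p.rsw);
  double dU = 0.5 * p.eps * (-p.n * pow_e(1.0 / rr, p.n, p.ni) / rr +
                             0.5 * sech2 * dx);
  return -dU / s;
}

static PotPars parse_pot(const List& pot) {
  PotPars p;
  std::string fam = as<std::string>(pot["family"]);
  p.family = (fam == "mie") ? 0 : 1;
  p.eps = as<double>(pot["epsilon"]);
  p.n = as<double>(pot["n"]);
  p.m = as<double>(pot["m"]);
  NumericVector sig = pot["sigma_pair"];
  for (int i = 0; i < 3; ++i) p.sigma[i] = sig[i];
  p.rsw = pot.containsElementNamed("r_sw") ? as<double>(pot["r_sw"]) : 0.0;
  p.ni = (p.n == std::floor(p.n) && p.n > 0 && p.n < 1024)
             ? static_cast<int>(p.n) : -1;
  p.mi = (p.m == std::floor(p.m) && p.m > 0 && p.m < 1024)
             ? static_cast<int>(p.m) : -1;
  p.rc = as<double>(pot["cutoff"]);
  if (p.family == 0) {
    p.prefac = (p.n / (p.n - p.m)) * std::pow(p.n / p.m, p.m / (p.n - p.m));
  } else {
    p.prefac = 0.0;
  }
  for (int i = 0; i < 3; ++i) {
    p.shift[i] = 0.0;
    p.shift[i] = pot_u(p, i, p.rc * (1.0 - 1e-12));
  }
  return p;
}

// positions are wrapped into [0, L), so |d| < L and one branch suffices
static inline double min_image(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

// Visit all unordered pairs within cutoff; calls f(i, j, dx, dy, dz, r)
// with dx = xi - xj under minimum image.  Linked-cell search with reusable
// buffers; all-pairs fallback when the box holds fewer than 3 cells per
// dimension.
template <typename F>
static void for_pairs(const double* px, const double* py, const double* pz,
                      int N, double L, double cutoff, F f) {
  const double c2 = cutoff * cutoff;
  int nc = static_cast<int>(std::floor(L / cutoff));
  // cap the grid so memory stays O(N) for dilute systems in large boxes
  int nc_cap = std::max(3, static_cast<int>(std::cbrt(4.0 * N)) + 1);
  if (nc > nc_cap) nc = nc_cap;
  if (nc < 3) {
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = min_image(px[i] - px[j], L);
        double dy = min_image(py[i] - py[j], L);
        double dz = min_image(pz[i] - pz[j], L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < c2) f(i, j, dx, dy, dz, std::sqrt(r2));
      }
    return;
  }
  const double w = L / nc;
  const size_t ncell = static_cast<size_t>(nc) * nc * nc;
  static std::vector<int> head, nxt, cellof;
  head.assign(ncell, -1);
  nxt.resize(N);
  cellof.resize(N);
  for (int i = 0; i < N; ++i) {
    int cx = static_cast<int>(px[i] / w); if (cx >= nc) cx = nc - 1;
    int cy = static_cast<int>(py[i] / w); if (cy >= nc) cy = nc - 1;
    int cz = static_cast<int>(pz[i] / w); if (cz >= nc) cz = nc - 1;
    size_t c = (static_cast<size_t>(cx) * nc + cy) * nc + cz;
    cellof[i] = static_cast<int>(c);
    nxt[i] = head[c];
    head[c] = i;
  }
  // half the neighbour stencil (13 cells) + self
  static const int st[13][3] = {
      {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
      {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
      {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
  for (int cx = 0; cx < nc; ++cx)
    for (int cy = 0; cy < nc; ++cy)
      for (int cz = 0; cz < nc; ++cz) {
        size_t ca = (static_cast<size_t>(cx) * nc + cy) * nc + cz;
        int i0 = head[ca];
        if (i0 < 0) continue;
        for (int i = i0; i >= 0; i = nxt[i])
          for (int j = nxt[i]; j >= 0; j = nxt[j]) {
            double dx = min_image(px[i] - px[j], L);
            double dy = min_image(py[i] - py[j], L);
            double dz = min_image(pz[i] - pz[j], L);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < c2) f(i, j, dx, dy, dz, std::sqrt(r2));
          }
        for (int s = 0; s < 13; ++s) {
          int bx = (cx + st[s][0] + nc) % nc;
          int by = (cy + st[s][1] + nc) % nc;
          int bz = (cz + st[s][2] + nc) % nc;
          size_t cb = (static_cast<size_t>(bx) * nc + by) * nc + bz;
          for (int i = i0; i >= 0; i = nxt[i])
            for (int j = head[cb]; j >= 0; j = nxt[j]) {
              double dx = min_image(px[i] - px[j], L);
              double dy = min_image(py[i] - py[j], L);
              double dz = min_image(pz[i] - pz[j], L);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < c2) f(i, j, dx, dy, dz, std::sqrt(r2));
            }
        }
      }
}

// [[Rcpp::export]]
List neighbor_pairs_cpp(const NumericMatrix& pos, double L, double cutoff) {
  if (cutoff >= L / 2) stop("cutoff must be smaller than half the box edge");
  const int N = pos.nrow();
  const double* px = pos.begin();
  std::vector<int> I, J;
  std::vector<double> D, OX, OY, OZ;
  for_pairs(px, px + N, px + 2 * N, N, L, cutoff,
            [&](int i, int j, double dx, double dy, double dz, double r) {
              I.push_back(i + 1);
              J.push_back(j + 1);
              D.push_back(r);
              // image offset of j relative to i: raw - minimum image
              OX.push_back(std::round((pos(i, 0) - pos(j, 0)) / L));
              OY.push_back(std::round((pos(i, 1) - pos(j, 1)) / L));
              OZ.push_back(std::round((pos(i, 2) - pos(j, 2)) / L));
            });
  return List::create(_["i"] = wrap(I), _["j"] = wrap(J), _["dist"] = wrap(D),
                      _["off_x"] = wrap(OX), _["off_y"] = wrap(OY),
                      _["off_z"] = wrap(OZ));
}

// [[Rcpp::export]]
List pair_forces_cpp(const NumericMatrix& pos, const IntegerVector& species,
                     double L, const List& pot) {
  PotPars p = parse_pot(pot);
  if (p.rc >= L / 2) stop("potential cutoff must be smaller than L/2");
  const int N = pos.nrow();
  const double* px = pos.begin();
  NumericMatrix F(N, 3);
  double pe = 0.0;
  for_pairs(px, px + N, px + 2 * N, N, L, p.rc,
            [&](int i, int j, double dx, double dy, double dz, double r) {
              int type = species[i] + species[j];  // 0 aa, 1 ab, 2 bb
              double fr = pot_f(p, type, r);
              if (!std::isfinite(fr))
                stop("non-finite force between particles %d and %d (r = %g)",
                     i + 1, j + 1, r);
              pe += pot_u(p, type, r);
              double fx = fr * dx / r, fy = fr * dy / r, fz = fr * dz / r;
              F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
              F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz;
            });
  return List::create(_["forces"] = F, _["potential_energy"] = pe);
}

// BAOAB discretisation of m dv/dt = F - (m/zeta) v + f_B, noise covariance
// <f_B f_B'> = 2 m kT delta(t-t') / zeta.  Positions wrapped into [0, L).
// [[Rcpp::export]]
List langevin_run_cpp(NumericMatrix pos, NumericMatrix vel,
                      const IntegerVector& species, const NumericVector& mass,
                      double L, const List& pot, double dt, int n_steps,
                      double zeta, double kT, int save_every = 0,
                      bool noise = true, bool friction = true) {
  PotPars p = parse_pot(pot);
  if (p.rc >= L / 2) stop("potential cutoff must be smaller than L/2");
  pos = clone(pos);  // do not mutate the caller's frame
  vel = clone(vel);
  const int N = pos.nrow();
  RNGScope scope;

  double a = friction ? std::exp(-dt / zeta) : 1.0;
  double b = noise ? std::sqrt(std::max(0.0, 1.0 - a * a)) : 0.0;
  if (noise && !friction)
    stop("noise without friction is not a well-defined thermostat");

  NumericMatrix F(N, 3);
  double pe = 0.0;
  double* pxm = pos.begin();
  double* vxm = vel.begin();
  double* fxm = F.begin();
  const int* sp = species.begin();
  // fused energy + force for the Mie fast path (shared powers)
  const bool mie_fast = (p.family == 0 && p.ni > 0 && p.mi > 0);
  const int dnm = mie_fast ? p.ni - p.mi : 0;
  auto forces = [&]() {
    std::fill(F.begin(), F.end(), 0.0);
    pe = 0.0;
    for_pairs(pxm, pxm + N, pxm + 2 * N, N, L, p.rc,
              [&](int i, int j, double dx, double dy, double dz, double r) {
                int type = sp[i] + sp[j];
                double fr;
                if (mie_fast) {
                  double x = p.sigma[type] / r;
                  double xm = ipow(x, p.mi);
                  double xn = xm * ipow(x, dnm);
                  double ce = p.prefac * p.eps;
                  pe += ce * (xn - xm) - p.shift[type];
                  fr = ce * (p.n * xn - p.m * xm) / r;
                } else {
                  fr = pot_f(p, type, r);
                  pe += pot_u(p, type, r);
                }
                if (!std::isfinite(fr))
                  stop("non-finite force between particles %d and %d (r = %g)",
                       i + 1, j + 1, r);
                double fx = fr * dx / r, fy = fr * dy / r, fz = fr * dz / r;
                fxm[i] += fx; fxm[i + N] += fy; fxm[i + 2 * N] += fz;
                fxm[j] -= fx; fxm[j + N] -= fy; fxm[j + 2 * N] -= fz;
              });
  };
  forces();

  int n_save = (save_every > 0) ? n_steps / save_every : 0;
  List frames(n_save);
  NumericVector log_t(n_save), log_pe(n_save), log_ke(n_save);
  int isave = 0;

  const double* ms = mass.begin();
  for (int step = 0; step < n_steps; ++step) {
    for (int d = 0; d < 3; ++d) {  // B (half kick) + A (half drift)
      double* pv = vxm + d * N;
      double* pp = pxm + d * N;
      const double* pf = fxm + d * N;
      for (int i = 0; i < N; ++i) {
        pv[i] += 0.5 * dt / ms[i] * pf[i];
        pp[i] += 0.5 * dt * pv[i];
      }
    }
    if (b > 0.0) {  // O (exact Ornstein-Uhlenbeck)
      for (int i = 0; i < N; ++i) {
        double s = b * std::sqrt(kT / ms[i]);
        vxm[i] = a * vxm[i] + s * R::norm_rand();
        vxm[i + N] = a * vxm[i + N] + s * R::norm_rand();
        vxm[i + 2 * N] = a * vxm[i + 2 * N] + s * R::norm_rand();
      }
    } else if (a != 1.0) {
      for (int i = 0; i < 3 * N; ++i) vxm[i] *= a;
    }
    for (int d = 0; d < 3; ++d) {  // A (half drift) + wrap
      double* pv = vxm + d * N;
      double* pp = pxm + d * N;
      for (int i = 0; i < N; ++i) {
        pp[i] += 0.5 * dt * pv[i];
        pp[i] -= L * std::floor(pp[i] / L);
      }
    }
    forces();
    for (int d = 0; d < 3; ++d) {  // B (half kick)
      double* pv = vxm + d * N;
      const double* pf = fxm + d * N;
      for (int i = 0; i < N; ++i) pv[i] += 0.5 * dt / ms[i] * pf[i];
    }
    if (save_every > 0 && (step + 1) % save_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < N; ++i)
        ke += 0.5 * mass[i] * (vel(i, 0) * vel(i, 0) + vel(i, 1) * vel(i, 1) +
                               vel(i, 2) * vel(i, 2));
      frames[isave] = clone(pos);
      log_t[isave] = (step + 1) * dt;
      log_pe[isave] = pe;
      log_ke[isave] = ke;
      ++isave;
    }
  }
  double ke = 0.0;
  for (int i = 0; i < N; ++i)
    ke += 0.5 * mass[i] * (vel(i, 0) * vel(i, 0) + vel(i, 1) * vel(i, 1) +
                           vel(i, 2) * vel(i, 2));
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["potential_energy"] = pe, _["kinetic_energy"] = ke,
                      _["frames"] = frames, _["log_time"] = log_t,
                      _["log_pe"] = log_pe, _["log_ke"] = log_ke);
}
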