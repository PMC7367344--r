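// Coagulation-fragmentation master equation with constant aggregation kernel
// (K+ = 2) and event-based single-particle chipping at per-cluster rate
// 2*lambda.  Clusters aggregating past k_max deposit their mass into a
// non-interacting gel compartment.
//
// The aggregation gain is a self-convolution, evaluated by FFT over the
// "active window" [1, W]: concentrations beyond the advancing cluster-size
// front are zero (to below front_tol) and are excluded, so the cost per
// right-hand-side evaluation is O(W log W) rather than O(k_max log k_max).
#include <RcppArmadillo.h>
#include <fftw3.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::uword next_pow2(arma::uword n) {
  arma::uword p = 1;
  while (p < n) p <<= 1;
  return p;
}

// cached FFTW real-to-complex plans per transform size
struct FftPlan {
  int n;
  double* in;
  fftw_complex* out;
  fftw_plan fwd, bwd;
  explicit FftPlan(int n_) : n(n_) {
    in = fftw_alloc_real(n);
    out = fftw_alloc_complex(n / 2 + 1);
    fwd = fftw_plan_dft_r2c_1d(n, in, out, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_c2r_1d(n, out, in, FFTW_ESTIMATE);
  }
  ~FftPlan() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);
    fftw_free(in);
    fftw_free(out);
  }
};

static FftPlan& plan_for(int n) {
  static std::map<int, FftPlan*> cache;
  auto it = cache.find(n);
  if (it == cache.end())
    it = cache.emplace(n, new FftPlan(n)).first;
  return *it->second;
}

// self-convolution of x (length m) into conv (length >= 2m-1) via FFTW
static void self_conv(const double* x, arma::uword m, arma::vec& conv) {
  int nf = static_cast<int>(next_pow2(2 * m));
  FftPlan& p = plan_for(nf);
  std::copy(x, x + m, p.in);
  std::fill(p.in + m, p.in + nf, 0.0);
  fftw_execute(p.fwd);
  const int nc = nf / 2 + 1;
  for (int i = 0; i < nc; ++i) {  // square in place
    double re = p.out[i][0], im = p.out[i][1];
    p.out[i][0] = re * re - im * im;
    p.out[i][1] = 2.0 * re * im;
  }
  fftw_execute(p.bwd);
  conv.set_size(2 * m - 1);
  const double inv = 1.0 / nf;
  for (arma::uword i = 0; i < 2 * m - 1; ++i) conv(i) = p.in[i] * inv;
}

// dc/dt on the window [1, W] (sizes); front window chosen by the caller.
// c has full length K; entries beyond W are ignored (assumed ~0).
static void me_rhs(const arma::vec& c, double lambda, arma::uword W,
                   arma::vec& dc, double& dgel) {
  const arma::uword K = c.n_elem;
  const double N = arma::accu(c.head(W));

  // conv[p] = sum_{a+b=p} c_a c_b, 0-based, size (a+1)+(b+1) = p+2
  static arma::vec conv;
  self_conv(c.memptr(), W, conv);

  const arma::uword Wg = std::min<arma::uword>(2 * W, K);  // gains reach 2W
  dc.zeros(K);
  for (arma::uword k = 2; k <= Wg; ++k) dc(k - 1) = conv(k - 2);
  dc.head(Wg) -= 2.0 * N * c.head(Wg);

  // merges past K feed the gel sink
  dgel = 0.0;
  if (2 * W > K)
    for (arma::uword p = K - 1; p <= 2 * W - 2; ++p)
      dgel += static_cast<double>(p + 2) * conv(p);

  // chipping: every cluster k >= 2 emits one monomer at rate 2*lambda;
  // a dimer split yields two monomers
  if (lambda > 0.0 && K >= 2) {
    const double tl = 2.0 * lambda;
    for (arma::uword k = 2; k <= Wg; ++k) {
      double gain = (k < K) ? c(k) : 0.0;
      dc(k - 1) += tl * (gain - c(k - 1));
    }
    dc(0) += tl * (N - c(0)) + tl * c(1);
  }
}

// [[Rcpp::export]]
List me_rhs_cpp(const arma::vec& c, double lambda) {
  arma::vec dc; double dgel;
  me_rhs(c, lambda, c.n_elem, dc, dgel);
  return List::create(_["dcdt"] = dc, _["dgel"] = dgel);
}

// last size with c_k > tol (1-based); 0 if none
static arma::uword front_pos(const arma::vec& c, double tol) {
  for (arma::uword k = c.n_elem; k >= 1; --k)
    if (c(k - 1) > tol) return k;
  return 0;
}

// Cash-Karp RK45 with adaptive steps.  Stops at t_end, or earlier when
//  - the state is stationary (max |dc/dt| over the window < stat_tol),
//  - the classification front (c_k > class_tol) passes front_cap
//    (mass draining towards the gel sink: gel phase), or
//  - gel_mass exceeds gel_exit.
// [[Rcpp::export]]
List me_evolve_cpp(const arma::vec& c0, double gel0, double lambda,
                   double t_end, double rtol = 1e-8, double atol = 1e-14,
                   double stat_tol = -1.0, int front_cap = 0,
                   double gel_exit = -1.0, double front_tol = 1e-12,
                   double class_tol = 1e-8, double h0 = 1e-3,
                   int max_steps = 10000000) {
  static const double B21 = 1.0 / 5;
  static const double B31 = 3.0 / 40, B32 = 9.0 / 40;
  static const double B41 = 3.0 / 10, B42 = -9.0 / 10, B43 = 6.0 / 5;
  static const double B51 = -11.0 / 54, B52 = 5.0 / 2, B53 = -70.0 / 27,
                      B54 = 35.0 / 27;
  static const double B61 = 1631.0 / 55296, B62 = 175.0 / 512,
                      B63 = 575.0 / 13824, B64 = 44275.0 / 110592,
                      B65 = 253.0 / 4096;
  static const double C1 = 37.0 / 378, C3 = 250.0 / 621, C4 = 125.0 / 594,
                      C6 = 512.0 / 1771;
  static const double D1 = C1 - 2825.0 / 27648, D3 = C3 - 18575.0 / 48384,
                      D4 = C4 - 13525.0 / 55296, D5 = -277.0 / 14336,
                      D6 = C6 - 1.0 / 4;

  const arma::uword K = c0.n_elem;
  arma::vec c = c0;
  double gel = gel0, t = 0.0, h = h0;
  arma::vec k1, k2, k3, k4, k5, k6, ctmp, cnew, cerr;
  double g1, g2, g3, g4, g5, g6;
  std::string exit_reason = "t_end";
  int step = 0;

  arma::uword W = std::min<arma::uword>(K, front_pos(c, front_tol) + 64);
  if (W < 16) W = std::min<arma::uword>(16, K);
  me_rhs(c, lambda, W, k1, g1);

  while (t < t_end && step < max_steps) {
    if (h > t_end - t) h = t_end - t;

    ctmp = c + h * B21 * k1;
    me_rhs(ctmp, lambda, W, k2, g2);
    ctmp = c + h * (B31 * k1 + B32 * k2);
    me_rhs(ctmp, lambda, W, k3, g3);
    ctmp = c + h * (B41 * k1 + B42 * k2 + B43 * k3);
    me_rhs(ctmp, lambda, W, k4, g4);
    ctmp = c + h * (B51 * k1 + B52 * k2 + B53 * k3 + B54 * k4);
    me_rhs(ctmp, lambda, W, k5, g5);
    ctmp = c + h * (B61 * k1 + B62 * k2 + B63 * k3 + B64 * k4 + B65 * k5);
    me_rhs(ctmp, lambda, W, k6, g6);

    cnew = c + h * (C1 * k1 + C3 * k3 + C4 * k4 + C6 * k6);
    cerr = h * (D1 * k1 + D3 * k3 + D4 * k4 + D5 * k5 + D6 * k6);

    double errmax = 0.0;
    arma::uword Wg = std::min<arma::uword>(2 * W, K);
    for (arma::uword i = 0; i < Wg; ++i) {
      double sc = atol + rtol * std::max(std::abs(c(i)), std::abs(cnew(i)));
      errmax = std::max(errmax, std::abs(cerr(i)) / sc);
    }

    if (errmax <= 1.0) {  // accept
      t += h;
      c = cnew;
      for (arma::uword i = 0; i < Wg; ++i)
        if (c(i) < 0.0) c(i) = 0.0;  // clip FFT/integration round-off
      gel += h * (C1 * g1 + C3 * g3 + C4 * g4 + C6 * g6);
      ++step;

      W = std::min<arma::uword>(K, front_pos(c, front_tol) + 64);
      if (W < 16) W = std::min<arma::uword>(16, K);
      me_rhs(c, lambda, W, k1, g1);

      if (stat_tol > 0.0 && arma::abs(k1.head(Wg)).max() < stat_tol) {
        exit_reason = "stationary";
        break;
      }
      if (front_cap > 0 &&
          front_pos(c, class_tol) >= static_cast<arma::uword>(front_cap)) {
        exit_reason = "front";
        break;
      }
      if (gel_exit > 0.0 && gel > gel_exit) {
        exit_reason = "gel_mass";
        break;
      }
      double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      h *= std::min(5.0, fac);
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
      ++step;
    }
    if (h < 1e-12) stop("step size underflow in master-equation integrator");
  }
  if (step >= max_steps)
    stop("master-equation integrator exceeded max_steps before t_end");

  return List::create(_["c"] = c, _["gel_mass"] = gel, _["time"] = t,
                      _["steps"] = step,
                      _["stationary"] = (exit_reason == "stationary"),
                      _["exit_reason"] = exit_reason,
                      _["front"] = static_cast<int>(front_pos(c, class_tol)));
}

// Power-series coefficients c_k of the steady-state generating function.
// With P(z) = sum_k c_k z^k, Q = P - N (Q(0) = -N), the stationary Riccati
// equation  z Q^2 + 2 lambda (1-z) Q + 2 lambda (1-z)^2 N = 0  gives, by
// matching powers of z, the explicit recursion
//   q_k = q_{k-1} - [ (Q^2)_{k-1} + 2 lambda N e_k ] / (2 lambda),
// with e_1 = -2, e_2 = 1, e_k = 0 otherwise.
// Extended precision: the recursion cancels O(1) terms down to tail
// amplitudes ~1e-16, which double precision cannot resolve beyond ~4 k_c.
// [[Rcpp::export]]
arma::vec me_series_cpp(double lambda, double N, int k_max) {
  std::vector<long double> q(k_max + 1);
  q[0] = -static_cast<long double>(N);
  const long double tl = 2.0L * lambda;
  arma::vec out(k_max);
  for (int k = 1; k <= k_max; ++k) {
    long double conv = 0.0L;  // (Q^2)_{k-1} = sum_{i+j=k-1} q_i q_j
    for (int i = 0; i <= k - 1; ++i) conv += q[i] * q[k - 1 - i];
    long double e = (k == 1) ? -2.0L : (k == 2) ? 1.0L : 0.0L;
    q[k] = q[k - 1] - (conv + tl * N * e) / tl;
    out(k - 1) = static_cast<double>(q[k]);
  }
  return out;  // c_1..c_kmax
}
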