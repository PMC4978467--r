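#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Three-state promoter cycle with a single saturable pause site:
//   dx1/dt = k_rec(t) * (1 - x1 - x2) - k_init * x1
//   dx2/dt = k_init * x1 - k_rel(t) * x2
// with k_rec(t) = kr*(1 + er*cos(w*(t - pr))), k_rel analogous. The system
// is linear with periodic coefficients; the unique periodic orbit is found
// from the monodromy of one period (affine map x -> Phi x + psi) and then
// recorded over one period with fixed-step RK4.

struct Rates {
  double kr, er, ki, kl, el;
  // cos/sin tables at all RK4 evaluation times (t and t+h/2), plus the
  // phase cosines so k(t) = k0*(1 + e*(cos_wt*cos_wp + sin_wt*sin_wp))
  std::vector<double> cwt, swt;
  double crp, srp, clp, slp;
};

static inline void rhs(const Rates& R, int tab, double x1, double x2,
                       double& d1, double& d2) {
  double mrec = R.cwt[tab] * R.crp + R.swt[tab] * R.srp;
  double mrel = R.cwt[tab] * R.clp + R.swt[tab] * R.slp;
  double krec = R.kr * (1.0 + R.er * mrec);
  double krel = R.kl * (1.0 + R.el * mrel);
  d1 = krec * (1.0 - x1 - x2) - R.ki * x1;
  d2 = R.ki * x1 - krel * x2;
}

// integrate one full period from (x1, x2); tables hold 2*n entries
// (index 2*i for t_i, 2*i+1 for t_i + h/2)
static void integrate_period(const Rates& R, int n, double h,
                             double& x1, double& x2,
                             double* orbit1 = nullptr, double* orbit2 = nullptr) {
  double k11, k12, k21, k22, k31, k32, k41, k42;
  for (int i = 0; i < n; ++i) {
    if (orbit1) { orbit1[i] = x1; orbit2[i] = x2; }
    int t0 = 2 * i, th = 2 * i + 1, t1 = (2 * i + 2) % (2 * n);
    rhs(R, t0, x1, x2, k11, k12);
    rhs(R, th, x1 + 0.5 * h * k11, x2 + 0.5 * h * k12, k21, k22);
    rhs(R, th, x1 + 0.5 * h * k21, x2 + 0.5 * h * k22, k31, k32);
    rhs(R, t1, x1 + h * k31, x2 + h * k32, k41, k42);
    x1 += h / 6.0 * (k11 + 2.0 * k21 + 2.0 * k31 + k41);
    x2 += h / 6.0 * (k12 + 2.0 * k22 + 2.0 * k32 + k42);
  }
}

// [[Rcpp::export(name = ".kinetics_periodic_cpp")]]
List kinetics_periodic_cpp(double kr, double er, double pr,
                           double ki, double kl, double el, double pl,
                           double period, int n_steps) {
  double w = 2.0 * M_PI / period;
  double h = period / n_steps;
  Rates R;
  R.kr = kr; R.er = er; R.ki = ki; R.kl = kl; R.el = el;
  R.crp = std::cos(w * pr); R.srp = std::sin(w * pr);
  R.clp = std::cos(w * pl); R.slp = std::sin(w * pl);
  R.cwt.resize(2 * n_steps);
  R.swt.resize(2 * n_steps);
  for (int i = 0; i < n_steps; ++i) {
    double t0 = i * h, th = t0 + 0.5 * h;
    R.cwt[2 * i] = std::cos(w * t0); R.swt[2 * i] = std::sin(w * t0);
    R.cwt[2 * i + 1] = std::cos(w * th); R.swt[2 * i + 1] = std::sin(w * th);
  }

  // monodromy of the affine period map
  double p1 = 0.0, p2 = 0.0;
  integrate_period(R, n_steps, h, p1, p2);              // psi
  double a1 = 1.0, a2 = 0.0;
  integrate_period(R, n_steps, h, a1, a2);              // Phi e1 + psi
  double b1 = 0.0, b2 = 1.0;
  integrate_period(R, n_steps, h, b1, b2);              // Phi e2 + psi
  double m11 = a1 - p1, m21 = a2 - p2, m12 = b1 - p1, m22 = b2 - p2;
  // solve (I - Phi) x = psi
  double A11 = 1.0 - m11, A12 = -m12, A21 = -m21, A22 = 1.0 - m22;
  double det = A11 * A22 - A12 * A21;
  if (std::fabs(det) < 1e-14) stop("periodic solve is singular");
  double x1 = (A22 * p1 - A12 * p2) / det;
  double x2 = (A11 * p2 - A21 * p1) / det;

  NumericVector o1(n_steps), o2(n_steps), tt(n_steps);
  double y1 = x1, y2 = x2;
  integrate_period(R, n_steps, h, y1, y2, o1.begin(), o2.begin());
  double resid = std::max(std::fabs(y1 - x1), std::fabs(y2 - x2));
  for (int i = 0; i < n_steps; ++i) tt[i] = i * h;
  return List::create(_["time"] = tt, _["x1"] = o1, _["x2"] = o2,
                      _["residual"] = resid);
}
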