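// Toy alchemical Hamiltonians and stochastic samplers (reduced units, k_B = 1).
//
// Kernel ids:
//   1  harmonic oscillator with lambda-interpolated spring constant
//   2  2D periodic micro-solvation system (LJ solvent + soft-core coupled solute)
//   3  two-component-lambda toy (soft-core LJ leg + scaled charge-like leg)
//
// All energies/forces are evaluated in double precision; the samplers use
// R's RNG so that results are reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pow6(double x) { double x2 = x * x; return x2 * x2 * x2; }

// soft-core distance (alpha sigma^6 lamfac^p + r^6)^(1/6)
static inline double sc_dist(double r, double sigma, double lamfac,
                             double alpha, double p) {
  double lp = (p == 1.0) ? lamfac : std::pow(lamfac, p);
  return std::pow(alpha * pow6(sigma) * lp + pow6(r), 1.0 / 6.0);
}

// d r_sc / d lamfac at fixed r
static inline double sc_dist_dlam(double rsc, double sigma, double lamfac,
                                  double alpha, double p) {
  double lp1 = (p == 1.0) ? 1.0 : p * std::pow(lamfac, p - 1.0);
  return alpha * pow6(sigma) * lp1 / (6.0 * rsc * rsc * rsc * rsc * rsc);
}

// d r_sc / d r at fixed lamfac
static inline double sc_dist_dr(double rsc, double r) {
  double r5 = r * r * r * r * r;
  double s5 = rsc * rsc * rsc * rsc * rsc;
  return r5 / s5;
}

static inline double vlj(double r, double eps, double sigma) {
  double sr6 = pow6(sigma / r);
  return 4.0 * eps * (sr6 * sr6 - sr6);
}

static inline double dvlj(double r, double eps, double sigma) {
  double sr6 = pow6(sigma / r);
  return 4.0 * eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
}

// ---------------------------------------------------------------------------
// system 1: harmonic, params = {kA, kB, n_osc}; x of length n_osc (independent
// oscillators sharing the interpolated spring constant), lambda of length 1.
// n_osc emulates system-size extensivity: energy gaps between neighboring
// lambda ensembles grow with n_osc, localizing the expanded-ensemble walk.
// ---------------------------------------------------------------------------

static inline double harm_k(const double* par, double lam) {
  return (1.0 - lam) * par[0] + lam * par[1];
}

// ---------------------------------------------------------------------------
// system 2: micro-solvation, params =
//   {n_solvent, box, eps_ss, sigma_ss, eps_sol, sigma_sol, q_sol, alpha, p}
// coordinates: 2*(n_solvent+1), solute first; lambda of length 1
// Solvent-solvent: plain LJ with minimum image, cutoff box/2.
// Solute-solvent: state A = ideal gas, state B = LJ + q/r, both evaluated at
// the shared soft-core distance r_B = (alpha sigma^6 (1-lambda)^p + r^6)^(1/6).
// ---------------------------------------------------------------------------

static inline double mi(double d, double box) {
  return d - box * std::round(d / box);
}

static double ms_energy(const double* par, const double* x, double lam) {
  int n = (int)par[0];
  double box = par[1], eps_ss = par[2], sig_ss = par[3];
  double eps_s = par[4], sig_s = par[5], q = par[6], alpha = par[7], p = par[8];
  double rc = 0.5 * box, e = 0.0;
  // solvent-solvent
  for (int i = 1; i <= n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      double dx = mi(x[2 * i] - x[2 * j], box);
      double dy = mi(x[2 * i + 1] - x[2 * j + 1], box);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < rc) e += vlj(r, eps_ss, sig_ss);
    }
  }
  // solute-solvent (soft-core, state A empty)
  for (int j = 1; j <= n; ++j) {
    double dx = mi(x[0] - x[2 * j], box);
    double dy = mi(x[1] - x[2 * j + 1], box);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < rc) {
      double rb = sc_dist(r, sig_s, 1.0 - lam, alpha, p);
      e += lam * (vlj(rb, eps_s, sig_s) + q / rb);
    }
  }
  return e;
}

static double ms_dhdl(const double* par, const double* x, double lam) {
  int n = (int)par[0];
  double box = par[1];
  double eps_s = par[4], sig_s = par[5], q = par[6], alpha = par[7], p = par[8];
  double rc = 0.5 * box, d = 0.0;
  for (int j = 1; j <= n; ++j) {
    double dx = mi(x[0] - x[2 * j], box);
    double dy = mi(x[1] - x[2 * j + 1], box);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < rc) {
      double rb = sc_dist(r, sig_s, 1.0 - lam, alpha, p);
      double vb = vlj(rb, eps_s, sig_s) + q / rb;
      double dvb = dvlj(rb, eps_s, sig_s) - q / (rb * rb);
      double drb = -sc_dist_dlam(rb, sig_s, 1.0 - lam, alpha, p);
      d += vb + lam * dvb * drb;
    }
  }
  return d;
}

static void ms_grad(const double* par, const double* x, double lam, double* g) {
  int n = (int)par[0];
  double box = par[1], eps_ss = par[2], sig_ss = par[3];
  double eps_s = par[4], sig_s = par[5], q = par[6], alpha = par[7], p = par[8];
  double rc = 0.5 * box;
  for (int i = 0; i < 2 * (n + 1); ++i) g[i] = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      double dx = mi(x[2 * i] - x[2 * j], box);
      double dy = mi(x[2 * i + 1] - x[2 * j + 1], box);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < rc && r > 0) {
        double dv = dvlj(r, eps_ss, sig_ss) / r;
        g[2 * i] += dv * dx;     g[2 * i + 1] += dv * dy;
        g[2 * j] -= dv * dx;     g[2 * j + 1] -= dv * dy;
      }
    }
  }
  for (int j = 1; j <= n; ++j) {
    double dx = mi(x[0] - x[2 * j], box);
    double dy = mi(x[1] - x[2 * j + 1], box);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < rc && r > 0) {
      double rb = sc_dist(r, sig_s, 1.0 - lam, alpha, p);
      double dvb = dvlj(rb, eps_s, sig_s) - q / (rb * rb);
      double dvdr = lam * dvb * sc_dist_dr(rb, r) / r;
      g[0] += dvdr * dx;         g[1] += dvdr * dy;
      g[2 * j] -= dvdr * dx;     g[2 * j + 1] -= dvdr * dy;
    }
  }
}

// ---------------------------------------------------------------------------
// system 3: two-lambda toy, params =
//   {k_t, r0, eps, sigma, q1, a_chan, alpha, p}
// coordinate: u (length 1); lambda = (lambda_coulomb, lambda_other)
// H = k_t (u - r0)^2 / 2 + lam_o * V_LJ(r_B) + q(lam_c) / r_B
// r_B = (alpha sigma^6 (1 - lam_o)^p + u^6)^(1/6)  (shared distance function)
// q(lam_c) integrates q'(l) = q1 (1 + a (2l-1)^2)/(1 + a/3); q(0)=0, q(1)=q1,
// so that the charge-force fluctuations dip at lam_c = 0.5 (metric channel).
// ---------------------------------------------------------------------------

static inline double tl_q(const double* par, double lc) {
  double q1 = par[4], a = par[5];
  return q1 * (lc + a * (std::pow(2.0 * lc - 1.0, 3.0) + 1.0) / 6.0) / (1.0 + a / 3.0);
}

static inline double tl_qp(const double* par, double lc) {
  double q1 = par[4], a = par[5];
  double t = 2.0 * lc - 1.0;
  return q1 * (1.0 + a * t * t) / (1.0 + a / 3.0);
}

static double tl_energy(const double* par, const double* x, const double* lam) {
  double kt = par[0], r0 = par[1], eps = par[2], sig = par[3];
  double alpha = par[6], p = par[7];
  double lc = lam[0], lo = lam[1], u = x[0];
  double rb = sc_dist(u, sig, 1.0 - lo, alpha, p);
  return 0.5 * kt * (u - r0) * (u - r0) + lo * vlj(rb, eps, sig) + tl_q(par, lc) / rb;
}

static void tl_dhdl(const double* par, const double* x, const double* lam, double* out) {
  double eps = par[2], sig = par[3], alpha = par[6], p = par[7];
  double lc = lam[0], lo = lam[1], u = x[0];
  double rb = sc_dist(u, sig, 1.0 - lo, alpha, p);
  double drb = -sc_dist_dlam(rb, sig, 1.0 - lo, alpha, p);
  out[0] = tl_qp(par, lc) / rb;
  out[1] = vlj(rb, eps, sig) + (lo * dvlj(rb, eps, sig) - tl_q(par, lc) / (rb * rb)) * drb;
}

static double tl_grad(const double* par, const double* x, const double* lam) {
  double kt = par[0], r0 = par[1], eps = par[2], sig = par[3];
  double alpha = par[6], p = par[7];
  double lc = lam[0], lo = lam[1], u = x[0];
  double rb = sc_dist(u, sig, 1.0 - lo, alpha, p);
  double dru = sc_dist_dr(rb, u);
  return kt * (u - r0) + (lo * dvlj(rb, eps, sig) - tl_q(par, lc) / (rb * rb)) * dru;
}

// ---------------------------------------------------------------------------
// dispatch
// ---------------------------------------------------------------------------

static int sys_dim(int id, const NumericVector& par) {
  if (id == 1) return (int)par[2];
  if (id == 2) return 2 * ((int)par[0] + 1);
  if (id == 3) return 1;
  stop("unknown kernel id %d", id);
}

static int sys_nlam(int id) { return id == 3 ? 2 : 1; }

static double sys_energy(int id, const double* par, const double* x, const double* lam) {
  if (id == 1) {
    double s2 = 0.0;
    for (int i = 0; i < (int)par[2]; ++i) s2 += x[i] * x[i];
    return 0.5 * harm_k(par, lam[0]) * s2;
  }
  if (id == 2) return ms_energy(par, x, lam[0]);
  if (id == 3) return tl_energy(par, x, lam);
  return NA_REAL;
}

static void sys_dhdl(int id, const double* par, const double* x, const double* lam, double* out) {
  if (id == 1) {
    double s2 = 0.0;
    for (int i = 0; i < (int)par[2]; ++i) s2 += x[i] * x[i];
    out[0] = 0.5 * (par[1] - par[0]) * s2;
    return;
  }
  if (id == 2) { out[0] = ms_dhdl(par, x, lam[0]); return; }
  if (id == 3) { tl_dhdl(par, x, lam, out); return; }
}

static void sys_grad(int id, const double* par, const double* x, const double* lam, double* out) {
  if (id == 1) {
    double k = harm_k(par, lam[0]);
    for (int i = 0; i < (int)par[2]; ++i) out[i] = k * x[i];
    return;
  }
  if (id == 2) { ms_grad(par, x, lam[0], out); return; }
  if (id == 3) { out[0] = tl_grad(par, x, lam); return; }
}

// [[Rcpp::export]]
double cpp_energy(int id, NumericVector par, NumericVector x, NumericVector lam) {
  return sys_energy(id, par.begin(), x.begin(), lam.begin());
}

// [[Rcpp::export]]
NumericVector cpp_dhdl(int id, NumericVector par, NumericVector x, NumericVector lam) {
  NumericVector out(sys_nlam(id));
  sys_dhdl(id, par.begin(), x.begin(), lam.begin(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gradient(int id, NumericVector par, NumericVector x, NumericVector lam) {
  NumericVector out(sys_dim(id, par));
  sys_grad(id, par.begin(), x.begin(), lam.begin(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// samplers
// ---------------------------------------------------------------------------

// one configuration move: overdamped Langevin Euler-Maruyama (0),
// Metropolis random walk (1), or the exact Ornstein-Uhlenbeck propagator of
// the overdamped dynamics (2; harmonic kernel only, linear force)
static void config_step(int id, const double* par, std::vector<double>& x,
                        const double* lam, double dt, double gamma, double beta,
                        int move_kind, double mc_step, std::vector<double>& g) {
  int d = (int)x.size();
  if (move_kind == 2) {
    if (id != 1) stop("exact_ou moves are only defined for the harmonic kernel");
    double k = harm_k(par, lam[0]);
    double a = std::exp(-k * dt / gamma);
    double s = std::sqrt((1.0 - a * a) / (beta * k));
    for (int i = 0; i < d; ++i) x[i] = a * x[i] + s * norm_rand();
    return;
  }
  if (move_kind == 0) {
    sys_grad(id, par, x.data(), lam, g.data());
    double c1 = dt / gamma, c2 = std::sqrt(2.0 * dt / (beta * gamma));
    for (int i = 0; i < d; ++i) {
      if (!std::isfinite(g[i])) stop("non-finite force encountered in Langevin step");
      x[i] += -c1 * g[i] + c2 * norm_rand();
    }
  } else {
    // Metropolis: single-particle move for the micro-solvation system,
    // whole-vector move otherwise
    double e0 = sys_energy(id, par, x.data(), lam);
    if (id == 2) {
      int npart = d / 2;
      int ip = (int)(unif_rand() * npart); if (ip >= npart) ip = npart - 1;
      double ox0 = x[2 * ip], ox1 = x[2 * ip + 1];
      x[2 * ip] += mc_step * (2.0 * unif_rand() - 1.0);
      x[2 * ip + 1] += mc_step * (2.0 * unif_rand() - 1.0);
      double e1 = sys_energy(id, par, x.data(), lam);
      if (!(unif_rand() < std::exp(-beta * (e1 - e0)))) { x[2 * ip] = ox0; x[2 * ip + 1] = ox1; }
    } else {
      std::vector<double> ox = x;
      for (int i = 0; i < d; ++i) x[i] += mc_step * (2.0 * unif_rand() - 1.0);
      double e1 = sys_energy(id, par, x.data(), lam);
      if (!(unif_rand() < std::exp(-beta * (e1 - e0)))) x = ox;
    }
  }
}

// Fixed-lambda run: samples dH/dlambda at the run's own lambda and the
// potential energy at every grid point (for BAR/MBAR energy differences).
// [[Rcpp::export]]
List cpp_run_fixed_lambda(int id, NumericVector par, NumericMatrix lambda_grid,
                          int ilam, NumericVector x0, int n_steps, double dt,
                          double gamma, double beta, int sample_interval,
                          bool store_configs, int move_kind, double mc_step) {
  RNGScope scope;
  int d = sys_dim(id, par), nl = sys_nlam(id), np = lambda_grid.nrow();
  if ((int)x0.size() != d) stop("x0 has length %d, expected %d", x0.size(), d);
  std::vector<double> x(x0.begin(), x0.end()), g(d);
  std::vector<double> lam(nl), lamj(nl);
  for (int k = 0; k < nl; ++k) lam[k] = lambda_grid(ilam, k);

  int n_samp = n_steps / sample_interval;
  NumericMatrix dhdl(n_samp, nl), ugrid(n_samp, np);
  NumericMatrix configs(store_configs ? n_samp : 1, store_configs ? d : 1);
  std::vector<double> dh(nl);
  int isamp = 0;
  for (int step = 1; step <= n_steps; ++step) {
    config_step(id, par.begin(), x, lam.data(), dt, gamma, beta, move_kind, mc_step, g);
    if (step % sample_interval == 0 && isamp < n_samp) {
      sys_dhdl(id, par.begin(), x.data(), lam.data(), dh.data());
      for (int k = 0; k < nl; ++k) dhdl(isamp, k) = dh[k];
      for (int j = 0; j < np; ++j) {
        for (int k = 0; k < nl; ++k) lamj[k] = lambda_grid(j, k);
        ugrid(isamp, j) = sys_energy(id, par.begin(), x.data(), lamj.data());
      }
      if (store_configs) for (int i = 0; i < d; ++i) configs(isamp, i) = x[i];
      ++isamp;
    }
  }
  NumericVector xf(x.begin(), x.end());
  return List::create(_["dhdl"] = dhdl, _["u_grid"] = ugrid,
                      _["configs"] = store_configs ? configs : NumericMatrix(0, 0),
                      _["x_final"] = xf);
}

// One expanded-ensemble epoch at frozen bias: alternates configuration steps
// with full-grid Gibbs lambda moves, accumulating the conditional weights
// w_lambda = P(lambda | x) that the diffusion metric needs.
// [[Rcpp::export]]
List cpp_run_ee_epoch(int id, NumericVector par, NumericMatrix lambda_grid,
                      NumericVector f, NumericVector pi_target, double beta,
                      NumericVector x0, int ilam0, int n_moves,
                      int steps_per_move, double dt, double gamma,
                      int sample_interval, bool record, int move_kind,
                      double mc_step) {
  RNGScope scope;
  int d = sys_dim(id, par), nl = sys_nlam(id), np = lambda_grid.nrow();
  if ((int)x0.size() != d) stop("x0 has length %d, expected %d", x0.size(), d);
  std::vector<double> x(x0.begin(), x0.end()), g(d), lamj(nl);
  std::vector<double> logw(np), w(np), dh(nl);
  std::vector<double> lpi(np);
  for (int j = 0; j < np; ++j) {
    if (pi_target[j] <= 0) stop("target distribution must be positive");
    lpi[j] = std::log(pi_target[j]);
  }
  int ilam = ilam0;
  int n_samp = record ? n_moves / sample_interval : 0;
  NumericVector whist(np), visits(np);
  NumericMatrix w_samples(std::max(n_samp, 1), np);
  NumericMatrix dhdl_grid(std::max(n_samp, 1), np * nl);
  IntegerVector ilam_trace(std::max(n_samp, 1));
  NumericVector xtrace(std::max(n_samp, 1));
  int isamp = 0;
  for (int m = 1; m <= n_moves; ++m) {
    for (int s = 0; s < steps_per_move; ++s) {
      for (int k = 0; k < nl; ++k) lamj[k] = lambda_grid(ilam, k);
      config_step(id, par.begin(), x, lamj.data(), dt, gamma, beta, move_kind, mc_step, g);
    }
    // conditional weights over the grid (max-shifted for stability)
    double wmax = -INFINITY;
    for (int j = 0; j < np; ++j) {
      for (int k = 0; k < nl; ++k) lamj[k] = lambda_grid(j, k);
      logw[j] = lpi[j] + f[j] - beta * sys_energy(id, par.begin(), x.data(), lamj.data());
      if (logw[j] > wmax) wmax = logw[j];
    }
    if (!std::isfinite(wmax)) stop("all lambda weights underflowed");
    double wsum = 0.0;
    for (int j = 0; j < np; ++j) { w[j] = std::exp(logw[j] - wmax); wsum += w[j]; }
    for (int j = 0; j < np; ++j) { w[j] /= wsum; whist[j] += w[j]; }
    // Gibbs move among all grid points
    double u = unif_rand(), acc = 0.0;
    ilam = np - 1;
    for (int j = 0; j < np; ++j) { acc += w[j]; if (u <= acc) { ilam = j; break; } }
    visits[ilam] += 1.0;
    if (record && m % sample_interval == 0 && isamp < n_samp) {
      for (int j = 0; j < np; ++j) {
        w_samples(isamp, j) = w[j];
        for (int k = 0; k < nl; ++k) lamj[k] = lambda_grid(j, k);
        sys_dhdl(id, par.begin(), x.data(), lamj.data(), dh.data());
        for (int k = 0; k < nl; ++k) dhdl_grid(isamp, j + k * np) = dh[k];
      }
      ilam_trace[isamp] = ilam + 1;  // 1-based for R
      xtrace[isamp] = x[0];
      ++isamp;
    }
  }
  NumericVector xf(x.begin(), x.end());
  return List::create(_["whist"] = whist, _["visits"] = visits,
                      _["n_moves"] = n_moves, _["w_samples"] = w_samples,
                      _["dhdl_grid"] = dhdl_grid, _["ilam_trace"] = ilam_trace,
                      _["xtrace"] = xtrace, _["x_final"] = xf,
                      _["ilam_final"] = ilam + 1, _["n_recorded"] = isamp);
}
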