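#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Overflow-safe logistic sigmoid.
inline double stable_sigmoid(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// Logistic time-variant gain, constrained to equal 1 at t = 0:
//   gamma(t) = sy * S(sx (t - d)) + S(sx d) + (1 - sy) * S(-sx d)
// where S is the logistic sigmoid. Algebraically identical to the
// two-term ratio form but safe for large |sx (t - d)|.
inline double gain_value(double t, double d, double sx, double sy) {
  return sy * stable_sigmoid(sx * (t - d)) +
         stable_sigmoid(sx * d) + (1.0 - sy) * stable_sigmoid(-sx * d);
}

// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector t, double d, double sx, double sy) {
  R_xlen_t n = t.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = gain_value(t[i], d, sx, sy);
  return out;
}

struct FptdResult {
  std::vector<double> t, fu, fl;
  double survival;
};

// Bernoulli function B(z) = z / (exp(z) - 1), the Scharfetter-Gummel
// weight; B(0) = 1, B(z) -> 0 for z -> +inf, B(z) -> -z for z -> -inf.
inline double bernoulli_fn(double z) {
  if (std::fabs(z) < 1e-5) return 1.0 - 0.5 * z + z * z / 12.0;
  if (z > 700.0) return 0.0;
  return z / std::expm1(z);
}

// Crank-Nicolson solve of the Fokker-Planck equation
//   dp/dt = -mu(t) dp/dx + (sigma(t)^2 / 2) d2p/dx2
// on x in (-1, 1) with absorbing boundaries, delta initial condition at 0.
// Coefficients are frozen at the midpoint time of each step. The first two
// steps use backward Euler (Rannacher start-up) to damp oscillations from
// the delta initial condition. Boundary fluxes are taken from the
// theta-weighted density so that absorbed + surviving mass balances exactly.
static FptdResult solve_fptd_core(double k, double sigma0, double d, double sx,
                                  double sy, bool gain_drift, bool gain_noise,
                                  bool noise_dep_c, double c, double dt,
                                  double t_max, int nx) {
  const double Z = 1.0;
  const double dx = 2.0 * Z / (nx + 1);
  const int nt = (int)std::lround(t_max / dt);
  std::vector<double> p(nx, 0.0), pnew(nx, 0.0);
  const int i0 = (nx - 1) / 2; // x = 0 grid point (nx odd)
  p[i0] = 1.0 / dx;            // unit mass

  const double mu0 = k * c;
  const double sig_base =
      noise_dep_c ? sigma0 * std::sqrt(1.0 + std::fabs(c)) : sigma0;

  FptdResult res;
  res.t.resize(nt);
  res.fu.resize(nt);
  res.fl.resize(nt);

  std::vector<double> rhs(nx), cp(nx), dpv(nx);

  for (int n = 0; n < nt; ++n) {
    const double tm = (n + 0.5) * dt;
    const double g = gain_value(tm, d, sx, sy);
    const double mu = gain_drift ? mu0 * g : mu0;
    const double sig = gain_noise ? sig_base * g : sig_base;
    double D = 0.5 * sig * sig;
    if (D < 1e-12) D = 1e-12;
    // Scharfetter-Gummel (exponential-fitting) discretization of the
    // advection-diffusion operator: central differencing at small cell
    // Peclet number, upwinding at large, positivity-friendly throughout.
    const double pe = mu * dx / D; // cell Peclet number
    const double Bp = bernoulli_fn(pe), Bm = bernoulli_fn(-pe);
    const double a = D / (dx * dx);
    const double ls = a * Bm, ld = -a * (Bp + Bm), lu = a * Bp;
    // Crank-Nicolson normally; backward Euler for the first two steps
    // (Rannacher start-up for the delta initial condition) and in
    // strongly advective regimes, where it is monotone.
    const double theta = (n < 2 || std::fabs(pe) > 2.0) ? 1.0 : 0.5;
    // A x = rhs with A = I - dt*theta*L, rhs = (I + dt*(1-theta)*L) p
    const double as = -dt * theta * ls, ad = 1.0 - dt * theta * ld,
                 au = -dt * theta * lu;
    const double bs = dt * (1.0 - theta) * ls,
                 bd = 1.0 + dt * (1.0 - theta) * ld,
                 bu = dt * (1.0 - theta) * lu;
    for (int i = 0; i < nx; ++i) {
      double r = bd * p[i];
      if (i > 0) r += bs * p[i - 1];
      if (i < nx - 1) r += bu * p[i + 1];
      rhs[i] = r;
    }
    // Thomas algorithm
    cp[0] = au / ad;
    dpv[0] = rhs[0] / ad;
    for (int i = 1; i < nx; ++i) {
      const double m = ad - as * cp[i - 1];
      cp[i] = au / m;
      dpv[i] = (rhs[i] - as * dpv[i - 1]) / m;
    }
    pnew[nx - 1] = dpv[nx - 1];
    for (int i = nx - 2; i >= 0; --i) pnew[i] = dpv[i] - cp[i] * pnew[i + 1];

    // boundary fluxes from the Scharfetter-Gummel flux into the absorbing
    // ghost nodes, evaluated on the theta-weighted density so that
    // absorbed + surviving mass balances exactly
    const double pu = theta * pnew[nx - 1] + (1.0 - theta) * p[nx - 1];
    const double pl = theta * pnew[0] + (1.0 - theta) * p[0];
    double fu = (D / dx) * Bm * pu;
    double fl = (D / dx) * Bp * pl;
    res.t[n] = tm;
    res.fu[n] = fu > 0.0 ? fu : 0.0;
    res.fl[n] = fl > 0.0 ? fl : 0.0;
    std::swap(p, pnew);
  }
  double mass = 0.0;
  for (int i = 0; i < nx; ++i) mass += (p[i] > 0.0 ? p[i] : 0.0);
  res.survival = mass * dx;
  return res;
}

// [[Rcpp::export]]
List cpp_solve_fptd(double k, double sigma0, double d, double sx, double sy,
                    bool gain_drift, bool gain_noise, bool noise_dep_c,
                    double c, double dt, double t_max, int nx) {
  FptdResult r = solve_fptd_core(k, sigma0, d, sx, sy, gain_drift, gain_noise,
                                 noise_dep_c, c, dt, t_max, nx);
  return List::create(
      _["t"] = NumericVector(r.t.begin(), r.t.end()),
      _["f_upper"] = NumericVector(r.fu.begin(), r.fu.end()),
      _["f_lower"] = NumericVector(r.fl.begin(), r.fl.end()),
      _["survival"] = r.survival);
}

// Convolve a boundary flux density with the residual-time kernel
// (Gaussian, bin-integrated on the dt grid), truncate below t = 0
// (and beyond the horizon), then renormalize to the input mass.
static void convolve_core(const std::vector<double> &f, std::vector<double> &out,
                          double dt, double mu, double sd) {
  const int n = (int)f.size();
  out.assign(n, 0.0);
  double mass_in = 0.0;
  for (int i = 0; i < n; ++i) mass_in += f[i];
  if (mass_in <= 0.0) return;
  if (sd <= 0.0) {
    const int shift = (int)std::lround(mu / dt);
    for (int i = 0; i < n; ++i) {
      const int j = i + shift;
      if (j >= 0 && j < n) out[j] = f[i];
    }
  } else {
    const int omin = (int)std::floor((mu - 6.0 * sd) / dt) - 1;
    const int omax = (int)std::ceil((mu + 6.0 * sd) / dt) + 1;
    std::vector<double> kern(omax - omin + 1);
    for (int o = omin; o <= omax; ++o) {
      const double hi = (o * dt + 0.5 * dt - mu) / sd;
      const double lo = (o * dt - 0.5 * dt - mu) / sd;
      kern[o - omin] = R::pnorm(hi, 0.0, 1.0, 1, 0) - R::pnorm(lo, 0.0, 1.0, 1, 0);
    }
    for (int i = 0; i < n; ++i) {
      if (f[i] <= 0.0) continue;
      for (int o = omin; o <= omax; ++o) {
        const int j = i + o;
        if (j >= 0 && j < n) out[j] += f[i] * kern[o - omin];
      }
    }
  }
  double mass_out = 0.0;
  for (int i = 0; i < n; ++i) mass_out += out[i];
  if (mass_out > 0.0) {
    const double s = mass_in / mass_out;
    for (int i = 0; i < n; ++i) out[i] *= s;
  }
}

// [[Rcpp::export]]
NumericVector cpp_convolve_residual(NumericVector f, double dt, double mu,
                                    double sd) {
  std::vector<double> fin(f.begin(), f.end()), out;
  convolve_core(fin, out, dt, mu, sd);
  return NumericVector(out.begin(), out.end());
}

// Robust trial-wise negative log likelihood: model RT density at each
// trial's (choice, rt), linearly interpolated on the solver time grid and
// floored at eps. par = (k, sigma0, d, sx, sy, t_res_mean, t_res_sd).
// [[Rcpp::export]]
double cpp_negloglik(NumericVector par, LogicalVector flags, NumericVector coh,
                     IntegerVector coh_idx, LogicalVector correct,
                     NumericVector rt, double dt, double t_max, int nx,
                     double eps) {
  const int ncoh = coh.size();
  const int ntr = rt.size();
  const int nt = (int)std::lround(t_max / dt);
  double nll = 0.0;
  for (int ci = 0; ci < ncoh; ++ci) {
    FptdResult r = solve_fptd_core(par[0], par[1], par[2], par[3], par[4],
                                   flags[0], flags[1], flags[2], coh[ci], dt,
                                   t_max, nx);
    std::vector<double> pu, pl;
    convolve_core(r.fu, pu, dt, par[5], par[6]);
    convolve_core(r.fl, pl, dt, par[5], par[6]);
    for (int i = 0; i < ntr; ++i) {
      if (coh_idx[i] != ci) continue;
      const std::vector<double> &dens = correct[i] ? pu : pl;
      // midpoint time grid t_j = (j + 0.5) dt
      double u = rt[i] / dt - 0.5;
      double v;
      if (u <= 0.0) {
        v = dens.empty() ? 0.0 : dens[0];
      } else if (u >= nt - 1) {
        v = (rt[i] <= t_max + 0.5 * dt) ? dens[nt - 1] : 0.0;
      } else {
        const int j = (int)std::floor(u);
        const double w = u - j;
        v = (1.0 - w) * dens[j] + w * dens[j + 1];
      }
      nll -= std::log(v > eps ? v : eps);
    }
  }
  return nll;
}

// Euler-Maruyama single-trial simulation; uses R's RNG so set.seed()
// controls reproducibility. Drift/noise frozen at step-midpoint times,
// matching the solver's convention. Discrete-time monitoring of a
// continuous barrier overestimates first-passage times by O(sqrt(dt)); the
// Broadie-Glasserman-Kou continuity correction (barrier moved inward by
// 0.5826 sigma(t) sqrt(dt)) removes the leading-order bias, and crossing
// times are assigned to the step midpoint.
// [[Rcpp::export]]
List cpp_simulate(double k, double sigma0, double d, double sx, double sy,
                  bool gain_drift, bool gain_noise, bool noise_dep_c, double c,
                  int n, double dt, double t_max, double t_res_mean,
                  double t_res_sd) {
  const int nt = (int)std::lround(t_max / dt);
  const double mu0 = k * c;
  const double sig_base =
      noise_dep_c ? sigma0 * std::sqrt(1.0 + std::fabs(c)) : sigma0;
  const double bgk = 0.5826; // zeta(1/2)/sqrt(2 pi)
  std::vector<double> mu_t(nt), sig_t(nt), zeff(nt);
  for (int s = 0; s < nt; ++s) {
    const double g = gain_value((s + 0.5) * dt, d, sx, sy);
    mu_t[s] = gain_drift ? mu0 * g : mu0;
    sig_t[s] = gain_noise ? sig_base * g : sig_base;
    double z = 1.0 - bgk * sig_t[s] * std::sqrt(dt);
    zeff[s] = z > 0.0 ? z : 0.0;
  }
  const double sqdt = std::sqrt(dt);
  LogicalVector correct(n), decided(n);
  NumericVector rtv(n);
  for (int i = 0; i < n; ++i) {
    double x = 0.0;
    bool dec = false, corr = false;
    double tdec = NA_REAL;
    for (int s = 0; s < nt; ++s) {
      x += mu_t[s] * dt + sqdt * sig_t[s] * norm_rand();
      if (x >= zeff[s] || x <= -zeff[s]) {
        dec = true;
        corr = (x >= zeff[s]);
        tdec = (s + 0.5) * dt;
        break;
      }
    }
    decided[i] = dec;
    correct[i] = corr;
    if (dec) {
      double tr;
      if (t_res_sd <= 0.0) {
        tr = t_res_mean;
      } else {
        do {
          tr = t_res_mean + t_res_sd * norm_rand();
        } while (tr < 0.0);
      }
      rtv[i] = tdec + tr;
    } else {
      rtv[i] = NA_REAL;
    }
  }
  return List::create(_["correct"] = correct, _["rt"] = rtv,
                      _["decided"] = decided);
}
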