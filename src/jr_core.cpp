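// Compiled integrators: Euler-Maruyama network simulator for the full
// two-subpopulation model, and an RK4 integrator (with variational equations)
// for the reduced single-subpopulation node used by the bifurcation toolkit.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sig(double v, double zmax, double r, double vth) {
  return zmax / (1.0 + std::exp(-r * (v - vth)));
}
static inline double dsig(double v, double zmax, double r, double vth) {
  double e = std::exp(-r * (v - vth));
  double d = 1.0 + e;
  return zmax * r * e / (d * d);
}

// ---------------------------------------------------------------------------
// Full network model.
//
// Per node: 12 states (x0,y0,x1,y1,x2,y2 for the alpha and gamma
// subpopulations) plus the plastic c4. Mixture variables
//   cx_k = r_alpha * x_k^alpha + mixture_sign * (1 - r_alpha) * x_k^gamma.
// Sigmoid arguments are the mixture variables (sigmoid_args = 0) or each
// subpopulation's own states (sigmoid_args = 1). The same node-level c4 enters
// both inhibitory loops; ISP senses the mixture firing rates.
// [[Rcpp::export]]
List jr_network_sim_cpp(NumericMatrix W, List pars, double dt, int n_steps,
                        double p_mean, double p_sd, double K, bool noise,
                        bool sde_scaling, bool record_subpop) {
  const int N = W.nrow();
  const double Aa = pars["A_alpha"], Ba = pars["B_alpha"];
  const double aa = pars["a_alpha"], ba = pars["b_alpha"];
  const double Ag = pars["A_gamma"], Bg = pars["B_gamma"];
  const double ag = pars["a_gamma"], bg = pars["b_gamma"];
  const double C = pars["C"], c1 = pars["c1"], c2 = pars["c2"],
               c3 = pars["c3"], c4_init = pars["c4_init"];
  const double zmax = pars["zeta_max"], rs = pars["slope"], vth = pars["v_th"];
  const double ra = pars["r_alpha"];
  const double msign = pars["mixture_sign"];
  const int s_args = pars["sigmoid_args"];           // 0 combined, 1 own
  const bool coup_Aa = pars["coupling_scaled_by_Aa"];
  const bool isp = pars["isp"];
  const double rho = pars["rho"], tau = pars["tau"], beta = pars["beta"],
               c4min = pars["c4_min"];

  const double wg = msign * (1.0 - ra);
  const double sd_eff = sde_scaling ? p_sd / std::sqrt(dt) : p_sd;

  // state layout per node: [0..5] alpha x0,y0,x1,y1,x2,y2; [6..11] gamma
  std::vector<double> y(12 * N, 0.0), d(12 * N), c4(N, c4_init);
  std::vector<double> zp(N), coup(N), pin(N);

  NumericMatrix eeg(n_steps, N), zpyr(n_steps, N), c4t(n_steps, N);
  NumericMatrix zpa, zpg;
  if (record_subpop) {
    zpa = NumericMatrix(n_steps, N);
    zpg = NumericMatrix(n_steps, N);
  }

  for (int k = 0; k < n_steps; ++k) {
    // node-level mixtures and pyramidal rates (coupling uses rates at step k)
    for (int i = 0; i < N; ++i) {
      const double *yi = &y[12 * i];
      double cx1 = ra * yi[2] + wg * yi[8];
      double cx2 = ra * yi[4] + wg * yi[10];
      zp[i] = sig(cx1 - cx2, zmax, rs, vth);
    }
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < N; ++j) s += W(i, j) * zp[j];
      coup[i] = K * C * s;
    }
    if (noise && sd_eff > 0.0) {
      NumericVector xi = Rcpp::rnorm(N, p_mean, sd_eff);
      for (int i = 0; i < N; ++i) pin[i] = xi[i];
    } else {
      for (int i = 0; i < N; ++i) pin[i] = p_mean;
    }

    for (int i = 0; i < N; ++i) {
      double *yi = &y[12 * i];
      double *di = &d[12 * i];
      const double cx0 = ra * yi[0] + wg * yi[6];
      const double cx1 = ra * yi[2] + wg * yi[8];
      const double cx2 = ra * yi[4] + wg * yi[10];

      for (int s = 0; s < 2; ++s) {
        const int o = 6 * s;
        const double A = s ? Ag : Aa, B = s ? Bg : Ba;
        const double a = s ? ag : aa, b = s ? bg : ba;
        double u0, upyr;
        if (s_args == 0) { u0 = cx0; upyr = cx1 - cx2; }
        else             { u0 = yi[o]; upyr = yi[o + 2] - yi[o + 4]; }
        const double cin = coup_Aa ? A * a * coup[i] : coup[i];
        di[o]     = yi[o + 1];
        di[o + 1] = A * a * sig(upyr, zmax, rs, vth)
                    - 2.0 * a * yi[o + 1] - a * a * yi[o];
        di[o + 2] = yi[o + 3];
        di[o + 3] = A * a * (pin[i] + c2 * sig(c1 * u0, zmax, rs, vth)) + cin
                    - 2.0 * a * yi[o + 3] - a * a * yi[o + 2];
        di[o + 4] = yi[o + 5];
        di[o + 5] = B * b * c4[i] * sig(c3 * u0, zmax, rs, vth)
                    - 2.0 * b * yi[o + 5] - b * b * yi[o + 4];
      }

      if (isp) {
        const double zinh = sig(c3 * cx0, zmax, rs, vth);
        const double g = std::pow((c4[i] - c4min) / C, beta);
        double c4n = c4[i] + dt * (zinh * (zp[i] - rho) * g) / tau;
        c4[i] = (c4n < c4min) ? c4min : c4n;
      }

      eeg(k, i) = cx1 - cx2;
      zpyr(k, i) = zp[i];
      c4t(k, i) = c4[i];
      if (record_subpop) {
        zpa(k, i) = sig(yi[2] - yi[4], zmax, rs, vth);
        zpg(k, i) = sig(yi[8] - yi[10], zmax, rs, vth);
      }
    }

    for (int i = 0; i < 12 * N; ++i) {
      y[i] += dt * d[i];
      if (!std::isfinite(y[i])) {
        stop("simulation diverged at step %d (t = %.3f s), node %d",
             k + 1, (k + 1) * dt, i / 12 + 1);
      }
    }
  }

  List out = List::create(_["eeg"] = eeg, _["zeta_pyr"] = zpyr,
                          _["c4"] = c4t);
  if (record_subpop) {
    out["zeta_pyr_alpha"] = zpa;
    out["zeta_pyr_gamma"] = zpg;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Reduced single-subpopulation node (6 states, 7 with ISP), deterministic.
// Parameter vector q:
//  [0] A [1] B [2] a [3] b [4] c1 [5] c2 [6] c3 [7] zeta_max [8] slope
//  [9] v_th [10] C [11] isp (0/1) [12] rho [13] tau [14] beta [15] c4_min
//  [16] c4_fixed (used when isp == 0)
static void reduced_rhs(const double *y, double p, const double *q, double *f) {
  const double A = q[0], B = q[1], a = q[2], b = q[3];
  const double c1 = q[4], c2 = q[5], c3 = q[6];
  const double zmax = q[7], r = q[8], vth = q[9], C = q[10];
  const bool isp = q[11] > 0.5;
  const double c4 = isp ? y[6] : q[16];
  const double u = y[2] - y[4];
  f[0] = y[1];
  f[1] = A * a * sig(u, zmax, r, vth) - 2.0 * a * y[1] - a * a * y[0];
  f[2] = y[3];
  f[3] = A * a * (p + c2 * sig(c1 * y[0], zmax, r, vth))
         - 2.0 * a * y[3] - a * a * y[2];
  f[4] = y[5];
  f[5] = B * b * c4 * sig(c3 * y[0], zmax, r, vth)
         - 2.0 * b * y[5] - b * b * y[4];
  if (isp) {
    const double g = std::pow((c4 - q[15]) / C, q[14]);
    f[6] = sig(c3 * y[0], zmax, r, vth) * (sig(u, zmax, r, vth) - q[12]) * g
           / q[13];
  }
}

// Analytic Jacobian, row-major n x n.
static void reduced_jac(const double *y, double p, const double *q, double *J,
                        int n) {
  (void)p;
  const double A = q[0], B = q[1], a = q[2], b = q[3];
  const double c1 = q[4], c2 = q[5], c3 = q[6];
  const double zmax = q[7], r = q[8], vth = q[9], C = q[10];
  const bool isp = q[11] > 0.5;
  const double c4 = isp ? y[6] : q[16];
  const double u = y[2] - y[4];
  const double Su = sig(u, zmax, r, vth), dSu = dsig(u, zmax, r, vth);
  const double S0 = sig(c3 * y[0], zmax, r, vth),
               dS0 = dsig(c3 * y[0], zmax, r, vth);
  const double dS1 = dsig(c1 * y[0], zmax, r, vth);
  for (int i = 0; i < n * n; ++i) J[i] = 0.0;
#define JJ(i, j) J[(i) * n + (j)]
  JJ(0, 1) = 1.0;
  JJ(1, 0) = -a * a;
  JJ(1, 1) = -2.0 * a;
  JJ(1, 2) = A * a * dSu;
  JJ(1, 4) = -A * a * dSu;
  JJ(2, 3) = 1.0;
  JJ(3, 0) = A * a * c2 * c1 * dS1;
  JJ(3, 2) = -a * a;
  JJ(3, 3) = -2.0 * a;
  JJ(4, 5) = 1.0;
  JJ(5, 0) = B * b * c4 * c3 * dS0;
  JJ(5, 4) = -b * b;
  JJ(5, 5) = -2.0 * b;
  if (isp) {
    const double g = std::pow((c4 - q[15]) / C, q[14]);
    const double dg = (q[14] <= 0.0) ? 0.0
      : q[14] * std::pow((c4 - q[15]) / C, q[14] - 1.0) / C;
    JJ(5, 6) = B * b * S0;
    JJ(6, 0) = c3 * dS0 * (Su - q[12]) * g / q[13];
    JJ(6, 2) = S0 * dSu * g / q[13];
    JJ(6, 4) = -S0 * dSu * g / q[13];
    JJ(6, 6) = S0 * (Su - q[12]) * dg / q[13];
  }
#undef JJ
}

// [[Rcpp::export]]
NumericVector reduced_rhs_cpp(NumericVector y, double p, NumericVector q) {
  const int n = y.size();
  NumericVector f(n);
  reduced_rhs(y.begin(), p, q.begin(), f.begin());
  return f;
}

// [[Rcpp::export]]
NumericMatrix reduced_jac_cpp(NumericVector y, double p, NumericVector q) {
  const int n = y.size();
  std::vector<double> J(n * n);
  reduced_jac(y.begin(), p, q.begin(), J.data(), n);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = J[i * n + j];
  return out;
}

// RK4 orbit of the reduced model; records every `stride` steps (0 = only the
// final state).
// [[Rcpp::export]]
List reduced_orbit_cpp(NumericVector y0, double p, NumericVector q, double dt,
                       int n_steps, int stride) {
  const int n = y0.size();
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  const int n_rec = stride > 0 ? n_steps / stride : 0;
  NumericMatrix traj(n_rec, n);
  int rec = 0;
  for (int k = 0; k < n_steps; ++k) {
    reduced_rhs(y.data(), p, q.begin(), k1.data());
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    reduced_rhs(tmp.data(), p, q.begin(), k2.data());
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    reduced_rhs(tmp.data(), p, q.begin(), k3.data());
    for (int i = 0; i < n; ++i) tmp[i] = y[i] + dt * k3[i];
    reduced_rhs(tmp.data(), p, q.begin(), k4.data());
    for (int i = 0; i < n; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (stride > 0 && (k + 1) % stride == 0 && rec < n_rec) {
      for (int i = 0; i < n; ++i) traj(rec, i) = y[i];
      ++rec;
    }
  }
  NumericVector yT(y.begin(), y.end());
  return List::create(_["y"] = yT, _["traj"] = traj);
}

// Flow map with variational equations: integrates y (n), the fundamental
// matrix Phi (n x n, Phi(0) = I) and the parameter sensitivity psi = dy/dp
// (n), using RK4 with the analytic Jacobian. Returns y(T), Phi(T), psi(T) and
// f(y(T)).
// [[Rcpp::export]]
List reduced_flow_cpp(NumericVector y0, double p, NumericVector q, double T,
                      int n_steps) {
  const int n = y0.size();
  const int m = n + n * n + n;  // y, Phi, psi
  const double dt = T / n_steps;
  std::vector<double> z(m, 0.0);
  for (int i = 0; i < n; ++i) z[i] = y0[i];
  for (int i = 0; i < n; ++i) z[n + i * n + i] = 1.0;  // Phi = I

  std::vector<double> k1(m), k2(m), k3(m), k4(m), tmp(m);
  std::vector<double> J(n * n), fp(n);

  auto rhs = [&](const double *zz, double *ff) {
    reduced_rhs(zz, p, q.begin(), ff);
    reduced_jac(zz, p, q.begin(), J.data(), n);
    // d Phi / dt = J Phi
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int l = 0; l < n; ++l) s += J[i * n + l] * zz[n + l * n + j];
        ff[n + i * n + j] = s;
      }
    // d psi / dt = J psi + df/dp ; df/dp = A*a in row 3 only
    const double Aa = q[0] * q[2];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int l = 0; l < n; ++l) s += J[i * n + l] * zz[n + n * n + l];
      ff[n + n * n + i] = s + (i == 3 ? Aa : 0.0);
    }
  };

  for (int k = 0; k < n_steps; ++k) {
    rhs(z.data(), k1.data());
    for (int i = 0; i < m; ++i) tmp[i] = z[i] + 0.5 * dt * k1[i];
    rhs(tmp.data(), k2.data());
    for (int i = 0; i < m; ++i) tmp[i] = z[i] + 0.5 * dt * k2[i];
    rhs(tmp.data(), k3.data());
    for (int i = 0; i < m; ++i) tmp[i] = z[i] + dt * k3[i];
    rhs(tmp.data(), k4.data());
    for (int i = 0; i < m; ++i)
      z[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }

  NumericVector yT(n), psi(n), fT(n);
  NumericMatrix Phi(n, n);
  for (int i = 0; i < n; ++i) yT[i] = z[i];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Phi(i, j) = z[n + i * n + j];
  for (int i = 0; i < n; ++i) psi[i] = z[n + n * n + i];
  reduced_rhs(z.data(), p, q.begin(), fp.data());
  for (int i = 0; i < n; ++i) fT[i] = fp[i];
  return List::create(_["y"] = yT, _["Phi"] = Phi, _["psi"] = psi,
                      _["f"] = fT);
}
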