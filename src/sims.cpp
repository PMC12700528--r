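// Stochastic Heun integrators for connectome-coupled neural mass models.
//
// All models share one contract:
//   * per-node counter-based RNG streams, so a G = 0 network run is
//     bit-identical to isolated single-node runs with the same node ids;
//   * stochastic Heun: predictor x~ = x + f(x) dt + dW, corrector
//     x' = x + dt/2 (f(x) + f(x~)) + dW with the same Wiener increment;
//   * divergence checks every recorded step, error names the step;
//   * thinning via record_every; transient removal is a feature-stage concern.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 streams, one per node, seeded from (seed, node_id).
// Box-Muller with a cached spare for normals.
// ---------------------------------------------------------------------------

struct NodeRng {
  uint64_t state;
  double spare;
  bool has_spare;

  static uint64_t mix(uint64_t z) {
    z += 0x9E3779B97F4A7C15ULL;
    uint64_t x = z;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
  }

  void seed(uint64_t master, uint64_t node_id) {
    // decorrelate streams by double-mixing the (seed, node) pair
    state = mix(mix(master) ^ (0xD1B54A32D192ED03ULL * (node_id + 1)));
    has_spare = false;
    spare = 0.0;
  }

  double unif() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t x = state;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    x ^= x >> 31;
    return (x >> 11) * 1.1102230246251565e-16; // 2^-53, in [0, 1)
  }

  double norm() {
    // Marsaglia polar method with a cached spare
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double v1, v2, s;
    do {
      v1 = 2.0 * unif() - 1.0;
      v2 = 2.0 * unif() - 1.0;
      s = v1 * v1 + v2 * v2;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v2 * f;
    has_spare = true;
    return v1 * f;
  }
};

static std::vector<NodeRng> make_streams(double seed, const IntegerVector& node_ids) {
  std::vector<NodeRng> rng(node_ids.size());
  for (int k = 0; k < node_ids.size(); ++k)
    rng[k].seed((uint64_t)seed, (uint64_t)node_ids[k]);
  return rng;
}

static void check_finite(const std::vector<double>& x, int step, const char* model) {
  for (size_t i = 0; i < x.size(); ++i)
    if (!R_finite(x[i]))
      stop("%s integration diverged (non-finite state) at step %d", model, step);
}

// Sparse row-major view of the coupling matrix (skip zero entries).
struct SparseSC {
  int n;
  std::vector<int> idx;     // column indices, rows concatenated
  std::vector<double> w;    // weights
  std::vector<int> start;   // row start offsets (length n + 1)

  SparseSC(const NumericMatrix& sc) {
    n = sc.nrow();
    start.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j)
        if (sc(i, j) != 0.0) ++start[i + 1];
    }
    for (int i = 0; i < n; ++i) start[i + 1] += start[i];
    idx.resize(start[n]);
    w.resize(start[n]);
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (sc(i, j) != 0.0) {
          idx[pos[i]] = j;
          w[pos[i]] = sc(i, j);
          ++pos[i];
        }
  }

  // y_i = sum_j SC_ij x_j
  void matvec(const std::vector<double>& x, std::vector<double>& y) const {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int p = start[i]; p < start[i + 1]; ++p) acc += w[p] * x[idx[p]];
      y[i] = acc;
    }
  }
};

static List sim_result(const NumericMatrix& states, double dt, int record_every,
                       int n_rec) {
  NumericVector time(n_rec);
  for (int t = 0; t < n_rec; ++t) time[t] = dt * record_every * (t + 1);
  return List::create(_["states"] = states, _["time"] = time);
}

// ---------------------------------------------------------------------------
// Wilson-Cowan
// ---------------------------------------------------------------------------

static inline double wc_sig(double x, double a, double b, double c, bool shifted) {
  double s = c / (1.0 + std::exp(-a * (x - b)));
  if (shifted) s -= c / (1.0 + std::exp(a * b));
  return s;
}

// [[Rcpp::export(name = ".cpp_sim_wilson_cowan")]]
List cpp_sim_wilson_cowan(NumericMatrix sc, List par, double duration, double dt,
                          double seed, int record_every, IntegerVector node_ids,
                          NumericVector E0, NumericVector I0, bool record_i) {
  const int n = sc.nrow();
  const double c_ee = par["c_ee"], c_ei = par["c_ei"], c_ie = par["c_ie"],
               c_ii = par["c_ii"], tau_e = par["tau_e"], tau_i = par["tau_i"],
               a_e = par["a_e"], a_i = par["a_i"], b_e = par["b_e"],
               b_i = par["b_i"], c_e = par["c_e"], c_i = par["c_i"],
               th_e = par["theta_e"], th_i = par["theta_i"], r_e = par["r_e"],
               r_i = par["r_i"], k_e = par["k_e"], k_i = par["k_i"],
               al_e = par["alpha_e"], al_i = par["alpha_i"], g_e = par["g_e"],
               g_i = par["g_i"], sigma = par["sigma"];
  const bool shifted = par["shifted_sigmoid"];
  NumericVector P = par["P"], Q = par["Q"];
  SparseSC S(sc);

  const int n_steps = (int)std::floor(duration / dt + 0.5);
  const int n_rec = n_steps / record_every;
  NumericMatrix out(record_i ? 2 * n : n, n_rec);
  std::vector<NodeRng> rng = make_streams(seed, node_ids);

  std::vector<double> E(E0.begin(), E0.end()), I(I0.begin(), I0.end());
  std::vector<double> cE(n), cI(n), fE(n), fI(n), pE(n), pI(n), dWe(n), dWi(n);
  const double sq = sigma * std::sqrt(dt);

  auto drift = [&](const std::vector<double>& e, const std::vector<double>& in,
                   const std::vector<double>& ce, const std::vector<double>& ci,
                   std::vector<double>& de, std::vector<double>& di) {
    for (int k = 0; k < n; ++k) {
      double xe = al_e * (c_ee * e[k] - c_ei * in[k] + P[k] - th_e + g_e * ce[k]);
      double xi = al_i * (c_ie * e[k] - c_ii * in[k] + Q[k] - th_i + g_i * ci[k]);
      de[k] = (-e[k] + (k_e - r_e * e[k]) * wc_sig(xe, a_e, b_e, c_e, shifted)) / tau_e;
      di[k] = (-in[k] + (k_i - r_i * in[k]) * wc_sig(xi, a_i, b_i, c_i, shifted)) / tau_i;
    }
  };

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (g_e != 0.0) S.matvec(E, cE); else std::fill(cE.begin(), cE.end(), 0.0);
    if (g_i != 0.0) S.matvec(I, cI); else std::fill(cI.begin(), cI.end(), 0.0);
    for (int k = 0; k < n; ++k) {
      dWe[k] = sq * rng[k].norm();
      dWi[k] = sq * rng[k].norm();
    }
    drift(E, I, cE, cI, fE, fI);
    for (int k = 0; k < n; ++k) {
      pE[k] = E[k] + fE[k] * dt + dWe[k];
      pI[k] = I[k] + fI[k] * dt + dWi[k];
    }
    // corrector drift at the predictor, coupling re-evaluated there
    std::vector<double> cE2(n, 0.0), cI2(n, 0.0), fE2(n), fI2(n);
    if (g_e != 0.0) S.matvec(pE, cE2);
    if (g_i != 0.0) S.matvec(pI, cI2);
    drift(pE, pI, cE2, cI2, fE2, fI2);
    for (int k = 0; k < n; ++k) {
      E[k] += 0.5 * dt * (fE[k] + fE2[k]) + dWe[k];
      I[k] += 0.5 * dt * (fI[k] + fI2[k]) + dWi[k];
    }
    if (step % record_every == 0) {
      check_finite(E, step, "Wilson-Cowan");
      check_finite(I, step, "Wilson-Cowan");
      for (int k = 0; k < n; ++k) out(k, rec) = E[k];
      if (record_i)
        for (int k = 0; k < n; ++k) out(n + k, rec) = I[k];
      ++rec;
    }
  }
  return sim_result(out, dt, record_every, n_rec);
}

// ---------------------------------------------------------------------------
// Jansen-Rit
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sim_jansen_rit")]]
List cpp_sim_jansen_rit(NumericMatrix sc, List par, double duration, double dt,
                        double seed, int record_every, IntegerVector node_ids,
                        NumericMatrix y_init) {
  const int n = sc.nrow();
  const double A = par["A"], B = par["B"], a = par["a"], b = par["b"],
               v_max = par["v_max"], v0 = par["v0"], r = par["r"],
               G = par["G"], P = par["P"], sigma = par["sigma"];
  NumericVector C = par["C"];
  SparseSC S(sc);

  auto sig = [&](double v) { return v_max / (1.0 + std::exp(r * (v0 - v))); };

  const int n_steps = (int)std::floor(duration / dt + 0.5);
  const int n_rec = n_steps / record_every;
  NumericMatrix out(n, n_rec);
  std::vector<NodeRng> rng = make_streams(seed, node_ids);

  // state layout: y0..y5 per node
  std::vector<std::vector<double>> y(6, std::vector<double>(n));
  for (int s = 0; s < 6; ++s)
    for (int k = 0; k < n; ++k) y[s][k] = y_init(s, k);

  std::vector<double> pyr(n), H(n), dW(n);
  std::vector<std::vector<double>> f(6, std::vector<double>(n)),
      f2(6, std::vector<double>(n)), yp(6, std::vector<double>(n));
  const double sq = A * a * sigma * std::sqrt(dt); // drive noise enters y4

  auto drift = [&](const std::vector<std::vector<double>>& Y,
                   std::vector<std::vector<double>>& D) {
    for (int k = 0; k < n; ++k) pyr[k] = sig(Y[1][k] - Y[2][k]);
    if (G != 0.0) S.matvec(pyr, H); else std::fill(H.begin(), H.end(), 0.0);
    for (int k = 0; k < n; ++k) {
      const double C1 = C[k], C2 = 0.8 * C[k], C3 = 0.25 * C[k], C4 = 0.25 * C[k];
      D[0][k] = Y[3][k];
      D[1][k] = Y[4][k];
      D[2][k] = Y[5][k];
      D[3][k] = A * a * pyr[k] - 2.0 * a * Y[3][k] - a * a * Y[0][k];
      D[4][k] = A * a * (P + C2 * sig(C1 * Y[0][k]) + G * H[k]) -
                2.0 * a * Y[4][k] - a * a * Y[1][k];
      D[5][k] = B * b * (C4 * sig(C3 * Y[0][k])) - 2.0 * b * Y[5][k] -
                b * b * Y[2][k];
    }
  };

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < n; ++k) dW[k] = sq * rng[k].norm();
    drift(y, f);
    for (int s = 0; s < 6; ++s)
      for (int k = 0; k < n; ++k) yp[s][k] = y[s][k] + f[s][k] * dt;
    for (int k = 0; k < n; ++k) yp[4][k] += dW[k];
    drift(yp, f2);
    for (int s = 0; s < 6; ++s)
      for (int k = 0; k < n; ++k) y[s][k] += 0.5 * dt * (f[s][k] + f2[s][k]);
    for (int k = 0; k < n; ++k) y[4][k] += dW[k];
    if (step % record_every == 0) {
      check_finite(y[1], step, "Jansen-Rit");
      check_finite(y[2], step, "Jansen-Rit");
      for (int k = 0; k < n; ++k) out(k, rec) = y[1][k] - y[2][k];
      ++rec;
    }
  }
  return sim_result(out, dt, record_every, n_rec);
}

// ---------------------------------------------------------------------------
// Stuart-Landau with per-pair conduction delays
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sim_stuart_landau")]]
List cpp_sim_stuart_landau(NumericMatrix sc, IntegerMatrix delay_steps, List par,
                           double duration, double dt, double seed,
                           int record_every, IntegerVector node_ids,
                           NumericVector x0, NumericVector y0) {
  const int n = sc.nrow();
  const double a = par["a"], G = par["G"], sigma = par["sigma"];
  NumericVector omega = par["omega"];

  int max_delay = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (delay_steps(i, j) > max_delay) max_delay = delay_steps(i, j);

  const int n_steps = (int)std::floor(duration / dt + 0.5);
  const int n_rec = n_steps / record_every;
  NumericMatrix out(n, n_rec);
  std::vector<NodeRng> rng = make_streams(seed, node_ids);

  // flat ring history (time-major), initialized by holding the initial state
  const int L = max_delay + 1;
  std::vector<double> hx((size_t)L * n), hy((size_t)L * n);
  for (int t = 0; t < L; ++t)
    for (int k = 0; k < n; ++k) {
      hx[(size_t)t * n + k] = x0[k];
      hy[(size_t)t * n + k] = y0[k];
    }
  std::vector<double> x(x0.begin(), x0.end()), yv(y0.begin(), y0.end());
  int head = 0; // position of the state at current time t

  // edge list with precomputed ring offsets per edge
  SparseSC S(sc);
  std::vector<int> elag(S.idx.size());
  for (int i = 0; i < n; ++i)
    for (int p = S.start[i]; p < S.start[i + 1]; ++p)
      elag[p] = delay_steps(i, S.idx[p]);

  std::vector<double> cx(n), cy(n), dWx(n), dWy(n), wsum(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int p = S.start[i]; p < S.start[i + 1]; ++p) wsum[i] += S.w[p];
  const double sq = sigma * std::sqrt(dt);

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // delayed coupling evaluated at time t, held for both Heun stages
    if (G != 0.0) {
      for (int i = 0; i < n; ++i) {
        double ax = 0.0, ay = 0.0;
        for (int p = S.start[i]; p < S.start[i + 1]; ++p) {
          int pos = head - elag[p];
          if (pos < 0) pos += L;
          const size_t off = (size_t)pos * n + S.idx[p];
          ax += S.w[p] * hx[off];
          ay += S.w[p] * hy[off];
        }
        cx[i] = G * (ax - wsum[i] * x[i]);
        cy[i] = G * (ay - wsum[i] * yv[i]);
      }
    } else {
      std::fill(cx.begin(), cx.end(), 0.0);
      std::fill(cy.begin(), cy.end(), 0.0);
    }
    for (int k = 0; k < n; ++k) {
      dWx[k] = sq * rng[k].norm();
      dWy[k] = sq * rng[k].norm();
      const double om = omega[k];
      double xi = x[k], yi = yv[k];
      double r2 = xi * xi + yi * yi;
      double fx = xi * (a - r2) - om * yi;
      double fy = yi * (a - r2) + om * xi;
      double px = xi + (fx + cx[k]) * dt + dWx[k];
      double py = yi + (fy + cy[k]) * dt + dWy[k];
      r2 = px * px + py * py;
      double fx2 = px * (a - r2) - om * py;
      double fy2 = py * (a - r2) + om * px;
      x[k] += 0.5 * dt * (fx + fx2 + 2.0 * cx[k]) + dWx[k];
      yv[k] += 0.5 * dt * (fy + fy2 + 2.0 * cy[k]) + dWy[k];
    }
    head = head + 1;
    if (head == L) head = 0;
    double* hxrow = &hx[(size_t)head * n];
    double* hyrow = &hy[(size_t)head * n];
    for (int k = 0; k < n; ++k) {
      hxrow[k] = x[k];
      hyrow[k] = yv[k];
    }
    if (step % record_every == 0) {
      check_finite(x, step, "Stuart-Landau");
      for (int k = 0; k < n; ++k) out(k, rec) = x[k];
      ++rec;
    }
  }
  return sim_result(out, dt, record_every, n_rec);
}

// ---------------------------------------------------------------------------
// 2D Epileptor (deterministic)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sim_epileptor2d")]]
List cpp_sim_epileptor2d(NumericMatrix sc, List par, double duration, double dt,
                         int record_every, NumericVector x0, NumericVector z0) {
  const int n = sc.nrow();
  const double I = par["I"], tau = par["tau"], G = par["G"];
  NumericVector eta = par["eta"];
  SparseSC S(sc);
  std::vector<double> rowsum(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int p = S.start[i]; p < S.start[i + 1]; ++p) rowsum[i] += S.w[p];

  const int n_steps = (int)std::floor(duration / dt + 0.5);
  const int n_rec = n_steps / record_every;
  NumericMatrix out(n, n_rec);

  std::vector<double> x(x0.begin(), x0.end()), z(z0.begin(), z0.end());
  std::vector<double> cp(n), fx(n), fz(n), fx2(n), fz2(n), px(n), pz(n);

  auto drift = [&](const std::vector<double>& X, const std::vector<double>& Z,
                   std::vector<double>& dx, std::vector<double>& dz) {
    if (G != 0.0) S.matvec(X, cp); else std::fill(cp.begin(), cp.end(), 0.0);
    for (int k = 0; k < n; ++k) {
      // sum_j SC_kj (x_j - x_k) = (SC x)_k - x_k * rowsum_k
      double diff = (G != 0.0) ? (cp[k] - X[k] * rowsum[k]) : 0.0;
      dx[k] = 1.0 - X[k] * X[k] * X[k] - 2.0 * X[k] * X[k] - Z[k] + I;
      dz[k] = (4.0 * (X[k] - eta[k]) - Z[k] - G * diff) / tau;
    }
  };

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    drift(x, z, fx, fz);
    for (int k = 0; k < n; ++k) {
      px[k] = x[k] + fx[k] * dt;
      pz[k] = z[k] + fz[k] * dt;
    }
    drift(px, pz, fx2, fz2);
    for (int k = 0; k < n; ++k) {
      x[k] += 0.5 * dt * (fx[k] + fx2[k]);
      z[k] += 0.5 * dt * (fz[k] + fz2[k]);
    }
    if (step % record_every == 0) {
      check_finite(x, step, "Epileptor");
      for (int k = 0; k < n; ++k) out(k, rec) = x[k];
      ++rec;
    }
  }
  return sim_result(out, dt, record_every, n_rec);
}

// ---------------------------------------------------------------------------
// Montbrio mean-field (r, v); noise enters the v equation only
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sim_montbrio")]]
List cpp_sim_montbrio(NumericMatrix sc, List par, double duration, double dt,
                      double seed, int record_every, IntegerVector node_ids,
                      NumericVector r0, NumericVector v0, bool record_v) {
  const int n = sc.nrow();
  const double tau = par["tau"], J = par["J"], Delta = par["Delta"],
               G = par["G"], sigma = par["sigma"], I_stim = par["I_stim"];
  NumericVector eta = par["eta"];
  SparseSC S(sc);

  const double pi = 3.14159265358979323846;
  const int n_steps = (int)std::floor(duration / dt + 0.5);
  const int n_rec = n_steps / record_every;
  NumericMatrix out(record_v ? 2 * n : n, n_rec);
  std::vector<NodeRng> rng = make_streams(seed, node_ids);

  std::vector<double> r(r0.begin(), r0.end()), v(v0.begin(), v0.end());
  std::vector<double> cp(n), dW(n);
  const double sq = sigma * std::sqrt(dt) / tau;

  auto fr = [&](double ri, double vi) {
    return (2.0 * ri * vi + Delta / (pi * tau)) / tau;
  };
  auto fv = [&](double ri, double vi, double couple, double et) {
    double pr = pi * tau * ri;
    return (vi * vi - pr * pr + J * tau * ri + et + couple + I_stim) / tau;
  };

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (G != 0.0) S.matvec(r, cp); else std::fill(cp.begin(), cp.end(), 0.0);
    for (int k = 0; k < n; ++k) {
      double couple = G * cp[k]; // frozen at t for this node's (re)tries
      dW[k] = sq * rng[k].norm();
      double f1r = fr(r[k], v[k]);
      double f1v = fv(r[k], v[k], couple, eta[k]);
      double prr = r[k] + f1r * dt;
      double pvv = v[k] + f1v * dt + dW[k];
      double f2r = fr(prr, pvv);
      double f2v = fv(prr, pvv, couple, eta[k]);
      double rn = r[k] + 0.5 * dt * (f1r + f2r);
      double vn = v[k] + 0.5 * dt * (f1v + f2v) + dW[k];
      if (rn <= 0.0) {
        // one retry with two half-steps, frozen coupling, fresh increments
        double rr = r[k], vv = v[k];
        double h = 0.5 * dt;
        for (int sub = 0; sub < 2; ++sub) {
          double dw = (sub == 0 ? dW[k] : sq * rng[k].norm()) * 0.70710678118654752;
          double g1r = fr(rr, vv), g1v = fv(rr, vv, couple, eta[k]);
          double qr = rr + g1r * h, qv = vv + g1v * h + dw;
          double g2r = fr(qr, qv), g2v = fv(qr, qv, couple, eta[k]);
          rr += 0.5 * h * (g1r + g2r);
          vv += 0.5 * h * (g1v + g2v) + dw;
        }
        rn = rr;
        vn = vv;
        if (rn <= 0.0)
          stop("Montbrio integration: firing rate r crossed zero at step %d; reduce dt", step);
      }
      r[k] = rn;
      v[k] = vn;
    }
    if (step % record_every == 0) {
      check_finite(r, step, "Montbrio");
      check_finite(v, step, "Montbrio");
      for (int k = 0; k < n; ++k) out(k, rec) = r[k];
      if (record_v)
        for (int k = 0; k < n; ++k) out(n + k, rec) = v[k];
      ++rec;
    }
  }
  return sim_result(out, dt, record_every, n_rec);
}

// ---------------------------------------------------------------------------
// Reduced Wong-Wang (synaptic gating S), with guarded transfer function
// ---------------------------------------------------------------------------

static inline double ww_transfer(double x, double a, double b, double d) {
  double u = a * x - b;
  double du = d * u;
  if (std::fabs(du) < 1e-6) return 1.0 / d + 0.5 * u; // removable singularity
  return u / (1.0 - std::exp(-du));
}

// [[Rcpp::export(name = ".cpp_ww_transfer")]]
NumericVector cpp_ww_transfer(NumericVector x, double a, double b, double d) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = ww_transfer(x[i], a, b, d);
  return out;
}

// [[Rcpp::export(name = ".cpp_sim_wong_wang")]]
List cpp_sim_wong_wang(NumericMatrix sc, List par, double duration, double dt,
                       double seed, int record_every, IntegerVector node_ids,
                       NumericVector S_init) {
  const int n = sc.nrow();
  const double a = par["a"], b = par["b"], d = par["d"], gamma = par["gamma"],
               tau_s = par["tau_s"], J = par["J"], G = par["G"];
  NumericVector w = par["w"], I = par["I"], sigma = par["sigma"];
  SparseSC Sp(sc);

  const int n_steps = (int)std::floor(duration / dt + 0.5);
  const int n_rec = n_steps / record_every;
  NumericMatrix out(n, n_rec);
  std::vector<NodeRng> rng = make_streams(seed, node_ids);

  std::vector<double> Sv(S_init.begin(), S_init.end());
  std::vector<double> cp(n), f1(n), f2(n), pS(n), dW(n);

  auto drift = [&](const std::vector<double>& Ss, const std::vector<double>& c,
                   std::vector<double>& D) {
    for (int k = 0; k < n; ++k) {
      double x = w[k] * J * Ss[k] + G * J * c[k] + I[k];
      D[k] = -Ss[k] / tau_s + (1.0 - Ss[k]) * gamma * ww_transfer(x, a, b, d);
    }
  };

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (G != 0.0) Sp.matvec(Sv, cp); else std::fill(cp.begin(), cp.end(), 0.0);
    for (int k = 0; k < n; ++k) dW[k] = sigma[k] * std::sqrt(dt) * rng[k].norm();
    drift(Sv, cp, f1);
    for (int k = 0; k < n; ++k) pS[k] = Sv[k] + f1[k] * dt + dW[k];
    std::vector<double> cp2(n, 0.0);
    if (G != 0.0) Sp.matvec(pS, cp2);
    drift(pS, cp2, f2);
    for (int k = 0; k < n; ++k) {
      Sv[k] += 0.5 * dt * (f1[k] + f2[k]) + dW[k];
      if (Sv[k] < 0.0) Sv[k] = 0.0; // physical range of a gating variable
      if (Sv[k] > 1.0) Sv[k] = 1.0;
    }
    if (step % record_every == 0) {
      check_finite(Sv, step, "Wong-Wang");
      for (int k = 0; k < n; ++k) out(k, rec) = Sv[k];
      ++rec;
    }
  }
  return sim_result(out, dt, record_every, n_rec);
}

// ---------------------------------------------------------------------------
// Balloon-Windkessel hemodynamics: states (s, f, v, q) per region,
// deterministic Heun at (dt * decimate) on block-averaged neural drive.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_bold_forward")]]
List cpp_bold_forward(NumericMatrix activity, double dt, List par, double TR,
                      int decimate) {
  const int n = activity.nrow();
  const int T = activity.ncol();
  const double tau_s = par["tau_s"], tau_f = par["tau_f"], alpha = par["alpha"],
               tau_0 = par["tau_0"], eps = par["epsilon_eff"], E_0 = par["E_0"],
               V_0 = par["V_0"], k1 = par["k1"], k2 = par["k2"], k3 = par["k3"];
  const double h = dt * decimate;
  const int n_steps = T / decimate;
  const double inv_alpha = 1.0 / alpha;

  const int stride = (int)std::floor(TR / h + 0.5);
  if (stride < 1) stop("TR must be at least the hemodynamic integration step");
  const int n_out = n_steps / stride;

  NumericMatrix bold(n, n_out);
  NumericVector time(n_out);
  for (int t = 0; t < n_out; ++t) time[t] = h * stride * (t + 1);

  for (int k = 0; k < n; ++k) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    int rec = 0;
    for (int step = 0; step < n_steps; ++step) {
      double x = 0.0;
      for (int j = 0; j < decimate; ++j) x += activity(k, step * decimate + j);
      x /= decimate;
      auto deriv = [&](double ss, double ff, double vv, double qq, double* D) {
        if (vv <= 0.0 || qq <= 0.0)
          stop("Balloon-Windkessel integration diverged (v or q <= 0) at step %d", step + 1);
        double fv = std::pow(vv, inv_alpha);
        D[0] = eps * x - ss / tau_s - (ff - 1.0) / tau_f;
        D[1] = ss;
        D[2] = (ff - fv) / tau_0;
        D[3] = (ff * (1.0 - std::pow(1.0 - E_0, 1.0 / ff)) / E_0 - fv * qq / vv) / tau_0;
      };
      double D1[4], D2[4];
      deriv(s, f, v, q, D1);
      double ps = s + h * D1[0], pf = f + h * D1[1], pv = v + h * D1[2],
             pq = q + h * D1[3];
      deriv(ps, pf, pv, pq, D2);
      s += 0.5 * h * (D1[0] + D2[0]);
      f += 0.5 * h * (D1[1] + D2[1]);
      v += 0.5 * h * (D1[2] + D2[2]);
      q += 0.5 * h * (D1[3] + D2[3]);
      if ((step + 1) % stride == 0 && rec < n_out) {
        double y = V_0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
        if (!R_finite(y))
          stop("Balloon-Windkessel integration diverged (non-finite BOLD) at step %d", step + 1);
        bold(k, rec) = y;
        ++rec;
      }
    }
  }
  return List::create(_["bold"] = bold, _["time"] = time);
}
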