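// Compiled cores: modal time integration of the rotating-plate equations and
// probabilistic spike generation. Both are O(T x n) inner loops over 10 kHz
// time series and are the only performance-critical paths in the package.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fixed-step RK4 for M qdd + C qd + (K + gy(t) G - gs(t) M) q = fx(t) Px + fy(t) Py.
// Time-varying coefficients are supplied on a half-step grid (length 2T + 1)
// so the RK4 stage evaluations use exact midpoint samples.
// Returns the modal displacement at the start of each step (T x m), or stops
// early with divergence information.
// [[Rcpp::export]]
List rk4_modal_cpp(const arma::mat& Minv, const arma::mat& K, const arma::mat& C,
                   const arma::mat& G, const arma::mat& M,
                   const arma::vec& Px, const arma::vec& Py,
                   const arma::vec& fx, const arma::vec& fy,
                   const arma::vec& gy, const arma::vec& gs,
                   double dt, int n_steps, int n_substeps, double q_max) {
  const int m = K.n_rows;
  arma::mat Q(n_steps, m, arma::fill::zeros);
  arma::vec q(m, arma::fill::zeros), v(m, arma::fill::zeros);
  const int nh = fx.n_elem;

  // linear interpolation on the half-step coefficient grid
  auto at = [nh](const arma::vec& s, double x) -> double {
    if (x <= 0.0) return s(0);
    if (x >= nh - 1) return s(nh - 1);
    const int i = (int)x; const double f = x - i;
    return (1.0 - f) * s(i) + f * s(i + 1);
  };
  // preallocated stage buffers (the inner loop is allocation-free)
  arma::vec k1q(m), k1v(m), k2q(m), k2v(m), k3q(m), k3v(m), k4q(m), k4v(m);
  arma::vec qt(m), vt(m), acc(m);
  auto accel = [&](double hx, const arma::vec& qq, const arma::vec& vv,
                   arma::vec& out) {
    acc = at(fx, hx) * Px + at(fy, hx) * Py;
    acc -= C * vv;
    acc -= K * qq;
    acc -= at(gy, hx) * (G * qq);
    acc += at(gs, hx) * (M * qq);
    out = Minv * acc;
  };

  const double h = dt / n_substeps;
  for (int t = 0; t < n_steps; ++t) {
    Q.row(t) = q.t();
    for (int s = 0; s < n_substeps; ++s) {
      const double h0 = 2.0 * t + 2.0 * s / n_substeps;
      const double h1 = h0 + 1.0 / n_substeps;
      const double h2 = h0 + 2.0 / n_substeps;
      k1q = v; accel(h0, q, v, k1v);
      k2q = v + 0.5 * h * k1v;
      qt = q + 0.5 * h * k1q; accel(h1, qt, k2q, k2v);
      k3q = v + 0.5 * h * k2v;
      qt = q + 0.5 * h * k2q; accel(h1, qt, k3q, k3v);
      k4q = v + h * k3v;
      qt = q + h * k3q; accel(h2, qt, k4q, k4v);
      q += h / 6.0 * (k1q + 2.0 * k2q + 2.0 * k3q + k4q);
      v += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    }
    if (!q.is_finite() || arma::abs(q).max() > q_max) {
      return List::create(_["q"] = Q, _["diverged"] = true, _["step"] = t + 1);
    }
  }
  return List::create(_["q"] = Q, _["diverged"] = false, _["step"] = n_steps);
}

// Draw a spike when P(fire) exceeds a standard-uniform draw, with an absolute
// refractory period: after a spike at step t0, the next spike is permitted at
// steps >= t0 + refr_steps (closed boundary). Draws use R's RNG, ordered
// location-major, then repeat, then time; draws are skipped where
// P < 1e-8 (expected spike loss from the cut is well below one event per encode).
static const double P_SKIP = 1e-8;

// First-spike-per-wingbeat encoder. g: filtered strain (T x n_loc block),
// already normalized. Applies the sigmoid nonlinearity internally to avoid
// materializing P. Returns first-spike times in ms (rows ordered
// repeat-major: row = rep * n_wb + wb) with 0 as the no-spike sentinel, and
// total spike counts per (repeat, location).
// [[Rcpp::export]]
List ln_encode_cpp(const arma::mat& g, double alpha, double beta,
                   int refr_steps, int wb_steps, int n_wb, int n_reps,
                   double dt_ms) {
  const int T = g.n_rows, n = g.n_cols;
  arma::mat fs(n_wb * n_reps, n, arma::fill::zeros);
  arma::imat counts(n_reps, n, arma::fill::zeros);
  std::vector<int> cand; cand.reserve(T);
  std::vector<double> pcand; pcand.reserve(T);
  // sigmoid argument below which P(fire) < P_SKIP and the draw is skipped
  // (small margin so the explicit p < P_SKIP test decides boundary cases,
  // keeping draw consumption identical to gen_spikes_cpp)
  const double g_floor = beta + std::log(P_SKIP) / alpha - 1e-6;

  for (int j = 0; j < n; ++j) {
    cand.clear(); pcand.clear();
    for (int t = 0; t < T; ++t) {
      const double gv = g(t, j);
      if (gv <= g_floor) continue;
      const double p = 1.0 / (1.0 + std::exp(-alpha * (gv - beta)));
      if (p < P_SKIP) continue;
      cand.push_back(t);
      pcand.push_back(p);
    }
    if (cand.empty()) continue;
    const int nc = (int)cand.size();
    for (int r = 0; r < n_reps; ++r) {
      int next_ok = 0;
      for (int c = 0; c < nc; ++c) {
        const int t = cand[c];
        if (t < next_ok) continue;
        if (pcand[c] > unif_rand()) {
          const int wb = t / wb_steps;
          if (wb < n_wb && fs(r * n_wb + wb, j) == 0.0) {
            const int within = t - wb * wb_steps;
            double tms = within * dt_ms;
            if (tms <= 0.0) tms = dt_ms;  // keep 0 free as the no-spike sentinel
            fs(r * n_wb + wb, j) = tms;
          }
          counts(r, j) += 1;
          next_ok = t + refr_steps;
        }
      }
    }
  }
  return List::create(_["first_spike"] = fs, _["counts"] = counts);
}

// Full raster variant for small inputs: returns a T x n x n_reps binary array.
// Same draw order and refractory convention as ln_encode_cpp, so identical
// seeds give identical spike trains when p matches the sigmoid output.
// [[Rcpp::export]]
IntegerVector gen_spikes_cpp(const arma::mat& p, int refr_steps, int n_reps) {
  const int T = p.n_rows, n = p.n_cols;
  IntegerVector out(Dimension(T, n, n_reps));
  for (int j = 0; j < n; ++j) {
    for (int r = 0; r < n_reps; ++r) {
      int next_ok = 0;
      for (int t = 0; t < T; ++t) {
        if (t < next_ok) continue;
        const double pv = p(t, j);
        if (pv < P_SKIP) continue;
        if (pv > unif_rand()) {
          out[t + T * (j + n * r)] = 1;
          next_ok = t + refr_steps;
        }
      }
    }
  }
  return out;
}
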