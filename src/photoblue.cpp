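#include <Rcpp.h>
using namespace Rcpp;

// Streaming multi-tau autocorrelator with symmetric normalization.
// Level 0 evaluates lags 1..m in base bins; each further level coarsens the
// trace by pairwise summation and evaluates lags m/2+1..m in coarsened bins.
// For a lag of k bins on a level trace c of length n (M = n - k overlapping
// pairs):
//   G(k) = M * sum_i c[i] c[i+k] / (sum_i c[i] * sum_i c[i+k]) - 1
// with both one-sided sums taken over the M overlapping positions. All
// accumulations are over integer photon counts, so they are exact in double.
// [[Rcpp::export(name = ".multitau_core")]]
DataFrame multitau_core(NumericVector counts, int m) {
  if (m < 2 || m % 2 != 0)
    stop("points per octave 'm' must be an even integer >= 2");
  std::vector<double> cur(counts.begin(), counts.end());
  std::vector<double> lag_bins;
  std::vector<double> G;
  int level = 0;
  double scale = 1.0; // base bins per current-level bin
  while ((int)cur.size() >= 2 * m) {
    int n = cur.size();
    int k_lo = (level == 0) ? 1 : m / 2 + 1;
    for (int k = k_lo; k <= m; ++k) {
      int M = n - k;
      if (M < m) continue;
      double sp = 0.0, sl = 0.0, sr = 0.0;
      for (int i = 0; i < M; ++i) {
        sp += cur[i] * cur[i + k];
        sl += cur[i];
        sr += cur[i + k];
      }
      if (sl <= 0.0 || sr <= 0.0) continue; // empty window: undefined
      lag_bins.push_back(k * scale);
      G.push_back((sp * (double)M) / (sl * sr) - 1.0);
    }
    // pairwise coarsening (drop a trailing odd bin)
    int half = cur.size() / 2;
    for (int i = 0; i < half; ++i) cur[i] = cur[2 * i] + cur[2 * i + 1];
    cur.resize(half);
    scale *= 2.0;
    ++level;
  }
  return DataFrame::create(Named("lag_bins") = lag_bins, Named("G") = G);
}

// Two-state (bright/dark) telegraph chain sampled at the bin grid.
// Stationary dark fraction T, correlation time tau expressed through the
// per-bin relaxation factor e = exp(-bin_time / tau):
//   P(dark  | bright) = T (1 - e),   P(dark | dark) = T + (1 - T) e.
// Uses the R RNG so the chain is reproducible under set.seed().
// [[Rcpp::export(name = ".telegraph_core")]]
IntegerVector telegraph_core(int n, double T, double relax) {
  IntegerVector bright(n);
  double p_d_given_b = T * (1.0 - relax);
  double p_d_given_d = T + (1.0 - T) * relax;
  int dark = (unif_rand() < T) ? 1 : 0;
  for (int i = 0; i < n; ++i) {
    bright[i] = dark ? 0 : 1;
    double p = dark ? p_d_given_d : p_d_given_b;
    dark = (unif_rand() < p) ? 1 : 0;
  }
  return bright;
}

// Brownian-diffusion FCS trace core: molecules random-walk in a periodic box
// (coordinates relative to the box center) and deposit expected photons
// peak * exp(-2 r^2 / omega0^2) per bin, optionally gated by a per-molecule
// bright/triplet telegraph chain. Uses the R RNG (reproducible under
// set.seed). The Gaussian profile is only evaluated within 3.5 omega0 of the
// beam; outside it is < 2e-11 of the peak.
// [[Rcpp::export(name = ".fcs_trace_core")]]
NumericVector fcs_trace_core(NumericMatrix pos0, int n_bins, double step_sd,
                             double omega0, double peak, double box,
                             double T, double relax) {
  NumericVector intensity(n_bins);
  double half = box / 2.0;
  double cut = 3.5 * omega0;
  double inv_w2 = 2.0 / (omega0 * omega0);
  bool triplet = T > 0.0;
  double p_d_given_b = T * (1.0 - relax);
  double p_d_given_d = T + (1.0 - T) * relax;
  for (int i = 0; i < pos0.nrow(); ++i) {
    double x = pos0(i, 0), y = pos0(i, 1);
    int dark = triplet && (unif_rand() < T) ? 1 : 0;
    for (int t = 0; t < n_bins; ++t) {
      if (step_sd > 0.0) {
        x += step_sd * norm_rand();
        y += step_sd * norm_rand();
        if (x > half) x -= box; else if (x < -half) x += box;
        if (y > half) y -= box; else if (y < -half) y += box;
      }
      if (triplet) {
        int was_dark = dark;
        dark = (unif_rand() < (was_dark ? p_d_given_d : p_d_given_b)) ? 1 : 0;
        if (was_dark) continue;
      }
      if (x > -cut && x < cut && y > -cut && y < cut)
        intensity[t] += peak * std::exp(-(x * x + y * y) * inv_w2);
    }
  }
  return intensity;
}

// Forward-Euler reference integrator for the three-state photoconversion
// kinetics red -> blue (k_blue), red -> dark (k_br), blue -> dark (k_bb).
// Records the state at the requested times (assumed sorted, >= 0). Serves as
// the independent cross-check for the closed-form solution.
// [[Rcpp::export(name = ".euler_kinetics_core")]]
NumericMatrix euler_kinetics_core(double k_blue, double k_br, double k_bb,
                                  NumericVector times, double dt) {
  int nt = times.size();
  NumericMatrix out(nt, 3);
  double r = 1.0, b = 0.0, d = 0.0, t = 0.0;
  for (int j = 0; j < nt; ++j) {
    long steps = (long)std::lround((times[j] - t) / dt);
    for (long s = 0; s < steps; ++s) {
      double dr = -(k_blue + k_br) * r;
      double db = k_blue * r - k_bb * b;
      double dd = k_br * r + k_bb * b;
      r += dt * dr;
      b += dt * db;
      d += dt * dd;
    }
    t = times[j];
    out(j, 0) = r;
    out(j, 1) = b;
    out(j, 2) = d;
  }
  return out;
}
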