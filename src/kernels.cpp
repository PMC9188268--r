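#include <Rcpp.h>
using namespace Rcpp;

// one-pole envelope smoother with separate attack/release coefficients
// [[Rcpp::export]]
NumericVector smooth_env_cpp(NumericVector x, double a_att, double a_rel) {
  int n = x.size();
  NumericVector y(n);
  double state = 0.0;
  for (int i = 0; i < n; ++i) {
    double a = (x[i] > state) ? a_att : a_rel;
    state = a * state + (1.0 - a) * x[i];
    y[i] = state;
  }
  return y;
}

// Event-driven leaky integrate-and-fire population stimulated by CI pulses.
//
// times/elec/amp: pulse events (sorted by time); spread: n_elec x n_cells
// attenuation matrix; each event increments every cell's membrane by
// amp * spread(elec, cell) after exponential leak decay since the previous
// event.  Spiking: membrane + Gaussian noise crosses an effective threshold
// raised by relative refractoriness; absolute refractoriness blocks spikes
// outright; emitted spike time = crossing time + latency + Gaussian jitter.
// [[Rcpp::export]]
List lif_population_cpp(NumericVector times, IntegerVector elec,
                        NumericVector amp, NumericMatrix spread,
                        double tau_m, double threshold, double t_abs,
                        double tau_rel, double rel_amp, double noise_sd,
                        double latency, double jitter_sd) {
  int n_ev = times.size();
  int n_cells = spread.ncol();
  std::vector<double> v(n_cells, 0.0);
  std::vector<double> t_last(n_cells, -1e9);   // last spike time
  std::vector<double> sp_t;
  std::vector<int> sp_c;
  double t_prev = (n_ev > 0) ? times[0] : 0.0;
  for (int i = 0; i < n_ev; ++i) {
    double t = times[i];
    double dt = t - t_prev;
    if (dt > 0) {
      double decay = std::exp(-dt / tau_m);
      for (int c = 0; c < n_cells; ++c) v[c] *= decay;
    }
    t_prev = t;
    int e = elec[i] - 1;
    double a = amp[i];
    for (int c = 0; c < n_cells; ++c) {
      if (t - t_last[c] < t_abs) continue;     // absolute refractory
      v[c] += a * spread(e, c);
      double noise = (noise_sd > 0) ? R::rnorm(0.0, noise_sd) : 0.0;
      double rel = t - t_last[c] - t_abs;
      double thr = threshold * (1.0 + rel_amp * std::exp(-rel / tau_rel));
      if (v[c] + noise >= thr) {
        double jit = (jitter_sd > 0) ? R::rnorm(0.0, jitter_sd) : 0.0;
        sp_t.push_back(t + latency + jit);
        sp_c.push_back(c + 1);
        v[c] = 0.0;
        t_last[c] = t;
      }
    }
  }
  return List::create(_["time"] = wrap(sp_t), _["cell"] = wrap(sp_c));
}

// same dynamics, but with an arbitrary per-event per-cell stimulus matrix
// (events x cells) -- the general "per-cell stimulus time series" contract
// [[Rcpp::export]]
List lif_population_dense_cpp(NumericVector times, NumericMatrix stim,
                              double tau_m, double threshold, double t_abs,
                              double tau_rel, double rel_amp,
                              double noise_sd, double latency,
                              double jitter_sd) {
  int n_ev = times.size();
  int n_cells = stim.ncol();
  std::vector<double> v(n_cells, 0.0);
  std::vector<double> t_last(n_cells, -1e9);
  std::vector<double> sp_t;
  std::vector<int> sp_c;
  double t_prev = (n_ev > 0) ? times[0] : 0.0;
  for (int i = 0; i < n_ev; ++i) {
    double t = times[i];
    double dt = t - t_prev;
    if (dt > 0) {
      double decay = std::exp(-dt / tau_m);
      for (int c = 0; c < n_cells; ++c) v[c] *= decay;
    }
    t_prev = t;
    for (int c = 0; c < n_cells; ++c) {
      if (t - t_last[c] < t_abs) continue;
      v[c] += stim(i, c);
      double noise = (noise_sd > 0) ? R::rnorm(0.0, noise_sd) : 0.0;
      double rel = t - t_last[c] - t_abs;
      double thr = threshold * (1.0 + rel_amp * std::exp(-rel / tau_rel));
      if (v[c] + noise >= thr) {
        double jit = (jitter_sd > 0) ? R::rnorm(0.0, jitter_sd) : 0.0;
        sp_t.push_back(t + latency + jit);
        sp_c.push_back(c + 1);
        v[c] = 0.0;
        t_last[c] = t;
      }
    }
  }
  return List::create(_["time"] = wrap(sp_t), _["cell"] = wrap(sp_c));
}
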