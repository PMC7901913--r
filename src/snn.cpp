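// Event-driven simulation of the two-layer LIF winner-take-all network
// and spike-train encoding. All times are in microseconds.
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rate-coded spike-train generation: inter-spike intervals drawn from a
// Normal distribution around 1/f (jittered-periodic, coefficient of
// variation cv) or, alternatively, Exponential (Poisson train). Uses R's
// RNG so results are reproducible with set.seed().
// [[Rcpp::export]]
List encode_spikes_cpp(NumericVector rates, double presentation_time,
                       double cv, double isi_floor, bool poisson) {
  std::vector<double> times;
  std::vector<int> px;
  const int n = rates.size();
  for (int p = 0; p < n; ++p) {
    const double f = rates[p];
    if (f <= 0) continue;
    const double mu = 1.0 / f;
    double t = 0.0;
    for (;;) {
      double isi = poisson ? R::rexp(mu) : R::rnorm(mu, cv * mu);
      if (isi < isi_floor) isi = isi_floor;
      t += isi;
      if (t > presentation_time) break;
      times.push_back(t);
      px.push_back(p + 1);  // 1-based pixel index
    }
  }
  // sort by time, ties by pixel index
  std::vector<int> ord(times.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (times[a] != times[b]) return times[a] < times[b];
    return px[a] < px[b];
  });
  NumericVector out_t(times.size());
  IntegerVector out_p(times.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    out_t[i] = times[ord[i]];
    out_p[i] = px[ord[i]];
  }
  return List::create(_["time"] = out_t, _["pixel"] = out_p);
}

struct FireEvent {
  double t;
  int neuron;
  long seq;  // insertion order for deterministic tie-breaking
};
struct FireLater {
  bool operator()(const FireEvent& a, const FireEvent& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.neuron != b.neuron) return a.neuron > b.neuron;
    return a.seq > b.seq;
  }
};

inline double clip01(double w) { return w < 0 ? 0 : (w > 1 ? 1 : w); }

// family: 0 = L_HB, 1 = NL_SB, 2 = NL_HB
inline double step_pot(double w, int family, double a, double g, double ws) {
  switch (family) {
    case 0: return clip01(w + a);
    case 1: return clip01(w + a * std::pow(1.0 - w, g));
    default: return clip01(w + (a / ws) * std::pow(1.0 - w * ws, g));
  }
}
inline double step_dep(double w, int family, double a, double g, double ws) {
  switch (family) {
    case 0: return clip01(w - a);
    case 1: return clip01(w - a * std::pow(w, g));
    default: return clip01(w - (a / ws) * std::pow(w * ws + 1.0 - ws, g));
  }
}

// One presentation: processes the (time-sorted) input spikes and the
// scheduled output fires in global time order. Membrane decay is applied
// lazily at integration time (exact for exponential leak). Returns the
// output spike records and, when plasticity is on, the updated weights.
// [[Rcpp::export]]
List present_cpp(NumericMatrix weights, NumericVector spike_t,
                 IntegerVector spike_px, NumericVector t_emit,
                 double tau_leak, double t_refrac, double t_inhibit,
                 double threshold, double t_stdp, bool stdp_on,
                 int family, double a_plus, double a_minus,
                 double g_plus, double g_minus,
                 double ws_plus, double ws_minus) {
  const int n_in = weights.nrow();
  const int n_out = weights.ncol();
  NumericMatrix w = stdp_on ? clone(weights) : weights;

  std::vector<double> membrane(n_out, 0.0), last_update(n_out, 0.0),
      refr_until(n_out, -1.0), inh_until(n_out, -1.0);
  std::vector<double> last_pre(n_in, -1e300);

  std::priority_queue<FireEvent, std::vector<FireEvent>, FireLater> fires;
  long seq = 0;

  std::vector<double> out_t;
  std::vector<int> out_n;

  const int n_spk = spike_t.size();
  int i = 0;
  while (i < n_spk || !fires.empty()) {
    bool do_fire = false;
    if (!fires.empty()) {
      if (i >= n_spk || fires.top().t <= spike_t[i]) do_fire = true;
    }
    if (do_fire) {
      FireEvent ev = fires.top();
      fires.pop();
      if (ev.t < inh_until[ev.neuron]) continue;  // lost the WTA race
      out_t.push_back(ev.t);
      out_n.push_back(ev.neuron + 1);
      refr_until[ev.neuron] = ev.t + t_refrac;
      for (int j = 0; j < n_out; ++j) {
        if (j == ev.neuron) continue;
        if (ev.t + t_inhibit > inh_until[j]) inh_until[j] = ev.t + t_inhibit;
      }
      if (stdp_on) {
        const double lo = ev.t - t_stdp;
        for (int p = 0; p < n_in; ++p) {
          const double tp = last_pre[p];
          double& wij = w(p, ev.neuron);
          if (tp >= lo && tp <= ev.t) {
            wij = step_pot(wij, family, a_plus, g_plus, ws_plus);
          } else {
            wij = step_dep(wij, family, a_minus, g_minus, ws_minus);
          }
        }
      }
    } else {
      const double t = spike_t[i];
      const int p = spike_px[i] - 1;
      ++i;
      last_pre[p] = t;  // recorded even when integration is blocked
      for (int j = 0; j < n_out; ++j) {
        if (t < refr_until[j] || t < inh_until[j]) continue;
        membrane[j] = membrane[j] * std::exp(-(t - last_update[j]) / tau_leak)
                      + w(p, j);
        last_update[j] = t;
        if (membrane[j] >= threshold) {
          fires.push({t + t_emit[j], j, seq++});
          membrane[j] = 0.0;
        }
      }
    }
  }

  return List::create(_["time"] = wrap(out_t), _["neuron"] = wrap(out_n),
                      _["weights"] = w);
}
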