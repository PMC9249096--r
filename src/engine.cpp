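// Compiled core: RK4 integration of the g_Ks-modulated conductance-based
// network with double-exponential synapses and optional asymmetric STDP.
//
// One call integrates one protocol segment (fixed g_Ks, fixed plasticity
// flag); callers chain segments by passing the returned state back in.
// External currents (drive, noise pulse, synaptic) are held constant across
// the four RK4 substages of a step, so the per-step update decouples across
// neurons and is done as scalar RK4 per cell.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct NP {
  double C, gna, gkdr, gks, gl, ena, ek, el, tauz;
};

// dState for one neuron; Iext = I_drive + I_noise - I_syn (uA/cm^2).
static inline void deriv(const NP &p, double V, double h, double n, double z,
                         double Iext, double &dV, double &dh, double &dn,
                         double &dz) {
  const double m = 1.0 / (1.0 + std::exp(-(V + 30.0) / 9.5));
  const double hinf = 1.0 / (1.0 + std::exp((V + 53.0) / 7.0));
  const double tauh = 0.37 + 2.78 / (1.0 + std::exp((V + 40.5) / 6.0));
  const double ninf = 1.0 / (1.0 + std::exp(-(V + 30.0) / 10.0));
  const double taun = 0.37 + 1.85 / (1.0 + std::exp((V + 27.0) / 15.0));
  const double zinf = 1.0 / (1.0 + std::exp(-(V + 39.0) / 5.0));
  dV = (-p.gna * m * m * m * h * (V - p.ena) - p.gkdr * n * n * n * n * (V - p.ek)
        - p.gks * z * (V - p.ek) - p.gl * (V - p.el) + Iext) / p.C;
  dh = (hinf - h) / tauh;
  dn = (ninf - n) / taun;
  dz = (zinf - z) / p.tauz;
}

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
List engine_run(NumericMatrix W_in, LogicalMatrix adj, LogicalVector is_inh,
                NumericVector V_in, NumericVector h_in, NumericVector n_in,
                NumericVector z_in, NumericVector sd_in, NumericVector sr_in,
                IntegerVector noise_count_in, NumericVector I_drive,
                List neuron_params, double dt, int n_steps, double t0,
                double noise_amp, double noise_prob, int noise_steps,
                double tau_d, double tau_r, double E_exc, double E_inh,
                bool stdp_on, double A_L, double tau_stdp, double w_max,
                double stdp_window, NumericVector hist_t_in,
                IntegerVector hist_id_in, bool record_vsum, bool record_v) {
  const int nn = W_in.nrow();
  NumericMatrix W = clone(W_in);
  NumericVector V = clone(V_in), h = clone(h_in), n = clone(n_in),
                z = clone(z_in), sd = clone(sd_in), sr = clone(sr_in);
  IntegerVector noise_count = clone(noise_count_in);

  NP p;
  p.C = as<double>(neuron_params["C"]);
  p.gna = as<double>(neuron_params["g_Na"]);
  p.gkdr = as<double>(neuron_params["g_Kdr"]);
  p.gks = as<double>(neuron_params["g_Ks"]);
  p.gl = as<double>(neuron_params["g_L"]);
  p.ena = as<double>(neuron_params["E_Na"]);
  p.ek = as<double>(neuron_params["E_K"]);
  p.el = as<double>(neuron_params["E_L"]);
  p.tauz = as<double>(neuron_params["tau_z"]);

  const double dd = std::exp(-dt / tau_d), dr = std::exp(-dt / tau_r);
  const bool any_inh = is_true(any(is_inh));

  // recent spikes (within the STDP window) carried across segments
  std::deque<std::pair<double, int> > hist;
  for (int k = 0; k < hist_t_in.size(); ++k)
    hist.push_back(std::make_pair(hist_t_in[k], hist_id_in[k]));

  std::vector<double> spk_t;
  std::vector<int> spk_id;
  std::vector<int> spikers;
  std::vector<double> ge(nn), gi(nn), Iext(nn), r(nn);

  NumericVector vsum(record_vsum ? n_steps : 0);
  NumericMatrix vtr(record_v ? n_steps : 0, record_v ? nn : 0);

  for (int k = 1; k <= n_steps; ++k) {
    const double t = t0 + k * dt;

    // synaptic kernel traces decay; conductances from active presyn columns
    std::fill(ge.begin(), ge.end(), 0.0);
    if (any_inh) std::fill(gi.begin(), gi.end(), 0.0);
    for (int j = 0; j < nn; ++j) {
      sd[j] *= dd;
      sr[j] *= dr;
      const double kern = sd[j] - sr[j];
      if (kern < 1e-12) continue;
      const double *col = &W(0, j);
      std::vector<double> &g = (any_inh && is_inh[j]) ? gi : ge;
      for (int i = 0; i < nn; ++i)
        if (col[i] != 0.0) g[i] += col[i] * kern;
    }

    // external currents, frozen for this step
    for (int i = 0; i < nn; ++i) {
      double Ino = 0.0;
      if (noise_prob > 0.0) {
        if (unif_rand() < noise_prob) noise_count[i] = noise_steps;
        if (noise_count[i] > 0) {
          Ino = noise_amp;
          --noise_count[i];
        }
      }
      double Isyn = ge[i] * (V[i] - E_exc);
      if (any_inh) Isyn += gi[i] * (V[i] - E_inh);
      Iext[i] = I_drive[i] + Ino - Isyn;
    }

    // classical RK4, per neuron
    spikers.clear();
    for (int i = 0; i < nn; ++i) {
      const double V0 = V[i], h0 = h[i], n0 = n[i], z0 = z[i];
      double k1v, k1h, k1n, k1z, k2v, k2h, k2n, k2z, k3v, k3h, k3n, k3z, k4v,
          k4h, k4n, k4z;
      deriv(p, V0, h0, n0, z0, Iext[i], k1v, k1h, k1n, k1z);
      deriv(p, V0 + 0.5 * dt * k1v, h0 + 0.5 * dt * k1h, n0 + 0.5 * dt * k1n,
            z0 + 0.5 * dt * k1z, Iext[i], k2v, k2h, k2n, k2z);
      deriv(p, V0 + 0.5 * dt * k2v, h0 + 0.5 * dt * k2h, n0 + 0.5 * dt * k2n,
            z0 + 0.5 * dt * k2z, Iext[i], k3v, k3h, k3n, k3z);
      deriv(p, V0 + dt * k3v, h0 + dt * k3h, n0 + dt * k3n, z0 + dt * k3z,
            Iext[i], k4v, k4h, k4n, k4z);
      const double Vn = V0 + dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      if (!std::isfinite(Vn))
        stop("non-finite membrane voltage for neuron %d at step %d", i + 1, k);
      V[i] = Vn;
      h[i] = clip01(h0 + dt / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h));
      n[i] = clip01(n0 + dt / 6.0 * (k1n + 2.0 * k2n + 2.0 * k3n + k4n));
      z[i] = clip01(z0 + dt / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z));
      if (V0 <= 0.0 && Vn > 0.0) spikers.push_back(i);
    }

    if (!spikers.empty()) {
      while (!hist.empty() && t - hist.front().first > stdp_window)
        hist.pop_front();
      // STDP first (history holds strictly earlier spikes: Dt = 0 excluded)
      if (stdp_on && A_L > 0.0) {
        std::fill(r.begin(), r.end(), 0.0);
        for (std::deque<std::pair<double, int> >::const_iterator it =
                 hist.begin();
             it != hist.end(); ++it)
          r[it->second] += std::exp(-(t - it->first) / tau_stdp);
        for (size_t s = 0; s < spikers.size(); ++s) {
          const int i = spikers[s]; // post spiked now: potentiate w[i, j]
          for (int j = 0; j < nn; ++j) {
            if (r[j] > 0.0 && adj(i, j)) {
              double w = W(i, j) + A_L * r[j];
              W(i, j) = w > w_max ? w_max : w;
            }
          }
        }
        for (size_t s = 0; s < spikers.size(); ++s) {
          const int j = spikers[s]; // pre spiked now: depress w[i, j]
          for (int i = 0; i < nn; ++i) {
            if (r[i] > 0.0 && adj(i, j)) {
              double w = W(i, j) - A_L * r[i];
              W(i, j) = w < 0.0 ? 0.0 : w;
            }
          }
        }
      }
      for (size_t s = 0; s < spikers.size(); ++s) {
        const int i = spikers[s];
        spk_t.push_back(t);
        spk_id.push_back(i + 1);
        sd[i] += 1.0;
        sr[i] += 1.0;
        hist.push_back(std::make_pair(t, i));
      }
    }

    if (record_vsum) {
      double s = 0.0;
      for (int i = 0; i < nn; ++i)
        if (!is_inh[i]) s += V[i];
      vsum[k - 1] = s;
    }
    if (record_v)
      for (int i = 0; i < nn; ++i) vtr(k - 1, i) = V[i];
  }

  const double t_end = t0 + n_steps * dt;
  while (!hist.empty() && t_end - hist.front().first > stdp_window)
    hist.pop_front();
  NumericVector ht(hist.size());
  IntegerVector hi(hist.size());
  for (size_t k = 0; k < hist.size(); ++k) {
    ht[k] = hist[k].first;
    hi[k] = hist[k].second;
  }

  return List::create(
      _["spike_times"] = wrap(spk_t), _["spike_neurons"] = wrap(spk_id),
      _["V"] = V, _["h"] = h, _["n"] = n, _["z"] = z, _["sd"] = sd,
      _["sr"] = sr, _["noise_count"] = noise_count, _["W"] = W,
      _["hist_t"] = ht, _["hist_id"] = hi, _["vsum"] = vsum,
      _["vtrace"] = vtr, _["t_end"] = t_end);
}
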