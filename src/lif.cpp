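#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Core LIF window simulator.
//
// Simulates a one- or two-layer network of leaky integrate-and-fire neurons
// continuously, segmented into n_windows windows of steps_per_window Euler
// steps each.  Membrane potential v resets at threshold and is clamped at
// v_r for ref_steps steps after a spike; the input drive u follows the same
// dynamics but never resets and is never clamped.  At each window start u is
// re-aligned to v and any residual refractory state is cleared, so that
// within a window the first threshold crossing of u coincides with the first
// spike of v (spike indicator H equals [Z >= theta] exactly).
//
// Noise convention: white-noise terms are unit-variance in continuous time;
// per-step samples are drawn with sd 1/sqrt(dt) so integrated variance is
// dt-invariant.  Layer-1 input: eta_i = x_dc + sigma*(sqrt(1-c)*xi_i +
// sqrt(c)*xi_common), weighted by w1[i].  Layer-2 input (if V given):
// eta_j = V[j,] . s_layer1(t) + sigma2*xi_j, weighted by w2[j].
//
// The synaptic trace decays as exp(-dt/tau_s) (exact) and jumps by syn_jump
// at each spike.
//
// Uses R's RNG (norm_rand), so results are reproducible under set.seed().
// [[Rcpp::export]]
List lif_kernel(int n_windows, int steps_per_window, double dt,
                double g_L, double theta, double v_r, int ref_steps,
                double tau_s, double syn_jump,
                NumericVector w1, double x_dc, double sigma, double c,
                Nullable<NumericMatrix> V_, Nullable<NumericVector> w2_,
                double sigma2,
                NumericVector v0, NumericVector s0,
                bool traces, bool record_spikes = false) {
  const int n1 = w1.size();
  NumericMatrix V;
  NumericVector w2;
  int n2 = 0;
  if (V_.isNotNull()) {
    V = as<NumericMatrix>(V_);
    n2 = V.nrow();
    if (V.ncol() != n1) stop("V must have one column per first-layer neuron");
    if (w2_.isNotNull()) {
      w2 = as<NumericVector>(w2_);
      if (w2.size() != n2) stop("w2 must have one entry per second-layer neuron");
    } else {
      w2 = NumericVector(n2, 1.0);
    }
  }
  const int n = n1 + n2;
  if (v0.size() != n || s0.size() != n)
    stop("v0 and s0 must have length equal to the total neuron count");

  const double isd   = 1.0 / std::sqrt(dt);
  const double sq1c  = std::sqrt(1.0 - c);
  const double sqc   = std::sqrt(c);
  const double sdec  = std::exp(-dt / tau_s);

  std::vector<double> v(n), u(n), s(n), eta(n), inp(n), Xacc(n), Zmax(n);
  std::vector<int> refc(n, 0), spiked(n, 0);
  for (int i = 0; i < n; ++i) { v[i] = v0[i]; s[i] = s0[i]; }

  NumericMatrix Z(n_windows, n), S(n_windows, n), X(n_windows, n);
  IntegerMatrix H(n_windows, n);

  const int n_steps_total = n_windows * steps_per_window;
  NumericMatrix v_tr, u_tr, s_tr;
  if (traces) {
    v_tr = NumericMatrix(n_steps_total, n);
    u_tr = NumericMatrix(n_steps_total, n);
    s_tr = NumericMatrix(n_steps_total, n);
  }

  std::vector< std::vector<double> > sp_times;
  if (record_spikes) sp_times.resize(n);

  RNGScope scope;
  int step_global = 0;
  for (int wdx = 0; wdx < n_windows; ++wdx) {
    // align window start: drive follows voltage, refractory cleared
    for (int i = 0; i < n; ++i) {
      u[i] = v[i];
      Zmax[i] = u[i];
      spiked[i] = 0;
      refc[i] = 0;
      Xacc[i] = 0.0;
    }
    for (int t = 0; t < steps_per_window; ++t, ++step_global) {
      double xi_common = norm_rand() * isd;
      for (int i = 0; i < n1; ++i) {
        double xi_i = norm_rand() * isd;
        eta[i] = x_dc + sigma * (sq1c * xi_i + sqc * xi_common);
        inp[i] = w1[i] * eta[i];
      }
      for (int j = 0; j < n2; ++j) {
        double drive = 0.0;
        for (int i = 0; i < n1; ++i) drive += V(j, i) * s[i];
        eta[n1 + j] = drive + sigma2 * norm_rand() * isd;
        inp[n1 + j] = w2[j] * eta[n1 + j];
      }
      for (int i = 0; i < n; ++i) {
        u[i] += dt * (-g_L * u[i] + inp[i]);
        int fired = 0;
        if (refc[i] > 0) {
          --refc[i];           // v clamped at v_r during refractory
        } else {
          v[i] += dt * (-g_L * v[i] + inp[i]);
          if (v[i] >= theta) {
            fired = 1;
            spiked[i] = 1;
            v[i] = v_r;
            refc[i] = ref_steps;
            if (record_spikes) sp_times[i].push_back((step_global + 1) * dt);
          }
        }
        s[i] = s[i] * sdec + syn_jump * fired;
        if (u[i] > Zmax[i]) Zmax[i] = u[i];
        Xacc[i] += eta[i];
        if (!std::isfinite(v[i]) || !std::isfinite(u[i]) || !std::isfinite(s[i]))
          stop("simulation diverged (non-finite state) at step %d, neuron %d",
               step_global + 1, i + 1);
        if (traces) {
          v_tr(step_global, i) = v[i];
          u_tr(step_global, i) = u[i];
          s_tr(step_global, i) = s[i];
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      Z(wdx, i) = Zmax[i];
      H(wdx, i) = spiked[i];
      S(wdx, i) = s[i];
      X(wdx, i) = Xacc[i] / steps_per_window;
    }
  }

  List out = List::create(
    _["Z"] = Z, _["H"] = H, _["S"] = S, _["X"] = X,
    _["v_final"] = NumericVector(v.begin(), v.end()),
    _["s_final"] = NumericVector(s.begin(), s.end()));
  if (traces) {
    out["v_trace"] = v_tr;
    out["u_trace"] = u_tr;
    out["s_trace"] = s_tr;
  }
  if (record_spikes) {
    List st(n);
    for (int i = 0; i < n; ++i)
      st[i] = NumericVector(sp_times[i].begin(), sp_times[i].end());
    out["spike_times"] = st;
  }
  return out;
}
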