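#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Clock-driven integration of a single integrate-and-fire neuron driven by a
// per-step current series (synaptic + noise already summed by the caller).
// The membrane equation is integrated with the exact exponential propagator
// of the linear ODE, holding the drive constant within each step; the
// non-leaky variant integrates the drive linearly.  Spike times are reported
// at the end of the step in which the threshold was crossed.
// [[Rcpp::export]]
NumericVector sim_neuron_cpp(NumericVector drive, double tau_m, double e_l,
                             double i_e, double v_reset, double v_th,
                             double v_min, double t_ref, bool leaky,
                             double v0, double dt) {
  const int n = drive.size();
  const double e_m = std::exp(-dt / tau_m);
  const int ref_steps = (int) std::lround(t_ref / dt);
  double v = v0;
  int refc = 0;
  std::vector<double> spikes;
  for (int t = 0; t < n; t++) {
    if (refc > 0) { v = v_reset; refc--; continue; }
    const double itot = i_e + drive[t];
    if (leaky) v = e_l + (v - e_l) * e_m + itot * (1.0 - e_m);
    else v += itot * dt / tau_m;
    if (v < v_min) v = v_min;
    if (v >= v_th) {
      spikes.push_back((t + 1) * dt);
      v = v_reset;
      refc = ref_steps;
    }
  }
  return wrap(spikes);
}

// One input pair through the fixed 2-2-1 circuit: neurons 0,1 are the input
// neurons (constant analog drive + optional per-step noise current), 2,3 the
// hidden pair, 4 the output.  Six connections in fixed order:
//   0: in0->h1, 1: in1->h1, 2: in0->h2, 3: in1->h2, 4: h1->out, 5: h2->out
// with weights already scaled by the weight gain.  Synapses carry a one-step
// transmission delay.  Dynamical synapses follow the quantal three-state
// short-term plasticity model (recovered x, active y, inactive 1-x-y) with
// utilization u; the postsynaptic current of a connection is weight * y.
// noise is an n_steps x 2 matrix of noise currents (pA) for the two input
// neurons, or a 0-row matrix for noise-free runs.
// [[Rcpp::export]]
List sim_xor_point_cpp(double drive0, double drive1, NumericVector bias,
                       NumericVector w, double tau_m, double e_l, double i_e,
                       double v_reset, double v_th, double v_min, double t_ref,
                       bool leaky, bool dynamical, double U, double tau_fac,
                       double tau_rec, double tau_syn, double dt, int n_steps,
                       NumericMatrix noise, bool record_spikes) {
  static const int pre[6]  = {0, 1, 0, 1, 2, 3};
  static const int post[6] = {2, 2, 3, 3, 4, 4};
  double V[5], drive[5], wl[6], bl[5];
  int refc[5], count[5];
  bool spiked[5], spiked_prev[5];
  double u[6], x[6], y[6], p[6];
  for (int nn = 0; nn < 5; nn++) {
    V[nn] = 0.0; refc[nn] = 0; count[nn] = 0; spiked_prev[nn] = false;
    bl[nn] = bias[nn];
  }
  drive[0] = drive0; drive[1] = drive1; drive[2] = drive[3] = drive[4] = 0.0;
  for (int c = 0; c < 6; c++) {
    u[c] = 0.0; x[c] = 1.0; y[c] = 0.0; p[c] = 0.0; wl[c] = w[c];
  }
  const double *noise_ptr = noise.nrow() > 0 ? noise.begin() : (const double *) 0;
  const int noise_n = noise.nrow();

  const double e_m   = std::exp(-dt / tau_m);
  const double e_syn = std::exp(-dt / tau_syn);
  const double e_rec = std::exp(-dt / tau_rec);
  const double e_fac = std::exp(-dt / tau_fac);
  // resource recovery sees the exponentially decaying active pool; the
  // tau_rec == tau_syn resonance is sidestepped by a negligible nudge
  double tr = tau_rec;
  if (std::fabs(tau_rec - tau_syn) < 1e-9 * tau_syn) tr = tau_syn * (1.0 + 1e-9);
  const double c1 = tau_syn / (tr - tau_syn);
  const int ref_steps = (int) std::lround(t_ref / dt);

  std::vector< std::vector<double> > sp;
  if (record_spikes) sp.assign(5, std::vector<double>());

  for (int t = 0; t < n_steps; t++) {
    // deliver last step's presynaptic spikes (one-step synaptic delay)
    if (spiked_prev[0] | spiked_prev[1] | spiked_prev[2] | spiked_prev[3]) {
      for (int c = 0; c < 6; c++) {
        if (spiked_prev[pre[c]]) {
          if (dynamical) {
            u[c] += U * (1.0 - u[c]);
            const double r = u[c] * x[c];
            x[c] -= r;
            y[c] += r;
            p[c] = wl[c] * y[c];
          } else {
            p[c] += wl[c];
          }
        }
      }
    }
    double isyn[5];
    isyn[0] = isyn[1] = 0.0;
    isyn[2] = p[0] + p[1];
    isyn[3] = p[2] + p[3];
    isyn[4] = p[4] + p[5];

    for (int nn = 0; nn < 5; nn++) {
      spiked[nn] = false;
      if (refc[nn] > 0) { V[nn] = v_reset; refc[nn]--; continue; }
      double itot = i_e + bl[nn] + drive[nn] + isyn[nn];
      if (noise_ptr && nn < 2) itot += noise_ptr[t + nn * noise_n];
      if (leaky) V[nn] = e_l + (V[nn] - e_l) * e_m + itot * (1.0 - e_m);
      else V[nn] += itot * dt / tau_m;
      if (V[nn] < v_min) V[nn] = v_min;
      if (V[nn] >= v_th) {
        spiked[nn] = true;
        count[nn]++;
        V[nn] = v_reset;
        refc[nn] = ref_steps;
        if (record_spikes) sp[nn].push_back((t + 1) * dt);
      }
    }

    // relax synapse state over the step
    if (dynamical) {
      for (int c = 0; c < 6; c++) {
        const double B = y[c] * c1;
        x[c] = 1.0 + (x[c] - 1.0 - B) * e_rec + B * e_syn;
        y[c] *= e_syn;
        u[c] *= e_fac;
        p[c] = wl[c] * y[c];
      }
    } else {
      for (int c = 0; c < 6; c++) p[c] *= e_syn;
    }
    for (int nn = 0; nn < 5; nn++) spiked_prev[nn] = spiked[nn];
  }

  IntegerVector counts(5);
  for (int nn = 0; nn < 5; nn++) counts[nn] = count[nn];
  List out = List::create(_["counts"] = counts);
  if (record_spikes) {
    List trains(5);
    for (int nn = 0; nn < 5; nn++) trains[nn] = wrap(sp[nn]);
    out["spikes"] = trains;
  }
  return out;
}
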