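#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Backward-Euler stepper for a passive multicompartment cable with
// Exp2Syn (double-exponential) synaptic conductances and a Boltzmann
// voltage-gated Ca readout on one compartment feeding a first-order
// decaying pool.  Units: mV, ms, nA, uS, nF (consistent: uS*mV = nA,
// nF*mV/ms = nA).  Synaptic conductance enters the matrix implicitly in
// voltage (evaluated at the new time), so the scheme stays stable for
// arbitrarily fast synapses.
//
// [[Rcpp::export]]
List cable_simulate_cpp(NumericVector cm_nF, NumericVector gl_uS,
                        double e_leak_mV, NumericVector ga_uS,
                        double dt_ms, int n_steps, double v0_mV,
                        IntegerVector syn_comp, NumericVector syn_gmax_uS,
                        double syn_tau_r_ms, double syn_tau_d_ms,
                        double syn_e_mV,
                        IntegerVector ev_step, IntegerVector ev_syn,
                        int inject_comp, NumericVector inject_nA,
                        IntegerVector ca_comps, double gca_uS, double eca_mV,
                        double ca_vhalf_mV, double ca_slope_mV,
                        double ca_k, double ca_tau_ms,
                        IntegerVector rec_comp, int rec_every) {
  const int n = cm_nF.size();
  const int n_syn = syn_comp.size();
  if (ga_uS.size() != n - 1) stop("ga_uS must have length n-1");

  std::vector<double> v(n, v0_mV);
  std::vector<double> A(n_syn, 0.0), B(n_syn, 0.0);
  const double dr = std::exp(-dt_ms / syn_tau_r_ms);
  const double dd = std::exp(-dt_ms / syn_tau_d_ms);
  const double t_pk = std::log(syn_tau_d_ms / syn_tau_r_ms) *
    syn_tau_r_ms * syn_tau_d_ms / (syn_tau_d_ms - syn_tau_r_ms);
  const double norm = 1.0 / (std::exp(-t_pk / syn_tau_d_ms) -
                             std::exp(-t_pk / syn_tau_r_ms));

  const int n_rec = n_steps / rec_every;
  NumericMatrix v_rec(n_rec, rec_comp.size());
  NumericVector ca_rec(n_rec);
  double ca = 0.0;

  // Thomas algorithm workspaces
  std::vector<double> diag(n), rhs(n), cp(n), dp(n);
  std::vector<double> base_diag(n);
  for (int i = 0; i < n; ++i) base_diag[i] = cm_nF[i] / dt_ms + gl_uS[i];
  for (int i = 0; i < n - 1; ++i) {
    base_diag[i] += ga_uS[i];
    base_diag[i + 1] += ga_uS[i];
  }

  int ev_i = 0;
  const int n_ev = ev_step.size();
  const bool has_inj = inject_nA.size() > 0;
  int rec_i = 0;

  for (int s = 0; s < n_steps; ++s) {
    // synapse state decay, then events scheduled for this step
    // (states are flushed to zero once negligible: avoids denormal
    // arithmetic stalls during the long silent stretches)
    for (int j = 0; j < n_syn; ++j) {
      A[j] = (A[j] > 1e-12) ? A[j] * dr : 0.0;
      B[j] = (B[j] > 1e-12) ? B[j] * dd : 0.0;
    }
    while (ev_i < n_ev && ev_step[ev_i] == s) {
      A[ev_syn[ev_i]] += 1.0;
      B[ev_syn[ev_i]] += 1.0;
      ++ev_i;
    }
    for (int i = 0; i < n; ++i) {
      diag[i] = base_diag[i];
      rhs[i] = cm_nF[i] / dt_ms * v[i] + gl_uS[i] * e_leak_mV;
    }
    for (int j = 0; j < n_syn; ++j) {
      const double g = syn_gmax_uS[j] * norm * (B[j] - A[j]);
      if (g > 0.0) {
        diag[syn_comp[j]] += g;
        rhs[syn_comp[j]] += g * syn_e_mV;
      }
    }
    if (has_inj) rhs[inject_comp] += inject_nA[s];

    // Thomas solve: sub/super diagonal is -ga
    if (n == 1) {
      v[0] = rhs[0] / diag[0];
    } else {
      cp[0] = -ga_uS[0] / diag[0];
      dp[0] = rhs[0] / diag[0];
      for (int i = 1; i < n; ++i) {
        const double a = -ga_uS[i - 1];
        const double m = diag[i] - a * cp[i - 1];
        cp[i] = (i < n - 1) ? -ga_uS[i] / m : 0.0;
        dp[i] = (rhs[i] - a * dp[i - 1]) / m;
      }
      v[n - 1] = dp[n - 1];
      for (int i = n - 2; i >= 0; --i) v[i] = dp[i] - cp[i] * v[i + 1];
    }
    if (!std::isfinite(v[0]))
      stop("numerical instability at step %d (dt = %g ms)", s, dt_ms);

    // Ca readout over the terminal section (does not feed back into
    // the voltage equation); gca_uS is per compartment
    double ica = 0.0;
    for (int k = 0; k < ca_comps.size(); ++k) {
      const double vc = v[ca_comps[k]];
      const double m_inf =
        1.0 / (1.0 + std::exp(-(vc - ca_vhalf_mV) / ca_slope_mV));
      ica += gca_uS * m_inf * (vc - eca_mV); // nA, negative inward
    }
    ca += dt_ms * (-ca_k * ica / ca_comps.size() - ca / ca_tau_ms);

    if ((s + 1) % rec_every == 0 && rec_i < n_rec) {
      for (int k = 0; k < rec_comp.size(); ++k)
        v_rec(rec_i, k) = v[rec_comp[k]];
      ca_rec[rec_i] = ca;
      ++rec_i;
    }
  }
  return List::create(_["v_rec"] = v_rec, _["ca_rec"] = ca_rec,
                      _["ca_final"] = ca);
}
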