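#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Euler integration of the theta-driven QIF excitatory-inhibitory network.
//
// tau_m dv/dt = v^2 + I_theta(t) + I_j + delta-pulse synaptic terms.
// A presynaptic spike through coupling g produces an instantaneous jump of
// 2g in the postsynaptic potential (the 2*tau_m factor on the pulse term
// cancels tau_m on the left-hand side). Spike when v >= vb, reset to -vb.
//
// Within-population connectivity is quenched and passed as out-edge
// adjacency lists (1-based from R); cross-population coupling is
// all-to-all, so an I spike shifts every E neuron by -2*gEI and an E spike
// shifts every I neuron by +2*gIE, and the GABA drive onto E cells is
// identical across the population (single shared state).
//
// The model LFP is accumulated online as sum_j |I_Aj| + |I_Gj| over E
// neurons, with double-exponential AMPA/GABA kinetics driven by the same
// spike trains (x jumps by 2*tauE*g/tau_rise per delivered spike).
// [[Rcpp::export(name = ".qif_sim_cpp")]]
List qif_sim_cpp(int nE, int nI,
                 double tauE, double tauI,
                 NumericVector Ie, NumericVector Ii,
                 double gEE, double gEI, double gIE, double gII,
                 List outEE, List outII,
                 double Atheta, double nu,
                 double vb, double dt, double dur_ms,
                 double record_dt,
                 double tauRA, double tauDA, double tauRG, double tauDG,
                 double transient_ms) {
  std::vector< std::vector<int> > adjEE(nE), adjII(nI);
  for (int l = 0; l < nE; ++l) {
    IntegerVector v = outEE[l];
    adjEE[l].assign(v.begin(), v.end());
    for (size_t k = 0; k < adjEE[l].size(); ++k) adjEE[l][k] -= 1;
  }
  for (int l = 0; l < nI; ++l) {
    IntegerVector v = outII[l];
    adjII[l].assign(v.begin(), v.end());
    for (size_t k = 0; k < adjII[l].size(); ++k) adjII[l][k] -= 1;
  }

  std::vector<double> vE(nE), vI(nI), xA(nE, 0.0), IA(nE, 0.0);
  double xG = 0.0, IG = 0.0;
  // deterministic staggered initial conditions in (-2, 0]; non-positive
  // values stay below the unstable fixed point of subthreshold neurons
  for (int j = 0; j < nE; ++j) vE[j] = -2.0 * (j + 0.5) / nE;
  for (int j = 0; j < nI; ++j) vI[j] = -2.0 * (j + 0.5) / nI;

  long nstep = (long)std::ceil(dur_ms / dt);
  int nrec = (int)std::floor((dur_ms - transient_ms) / record_dt);
  NumericVector lfp(nrec), vImean(nrec), theta_phase(nrec);
  std::vector<double> lfp_acc(nrec, 0.0), vI_acc(nrec, 0.0);
  std::vector<int> rec_n(nrec, 0);

  std::vector<double> spk_t;
  std::vector<int> spk_id;     // 1..nE are E, nE+1..nE+nI are I
  std::vector<int> spikesE, spikesI;
  const double twopi = 2.0 * M_PI;
  bool overflow = false;

  for (long s = 0; s < nstep && !overflow; ++s) {
    double t = s * dt;
    double Ith = Atheta * std::cos(twopi * nu * t / 1000.0);
    spikesE.clear(); spikesI.clear();
    for (int j = 0; j < nE; ++j) {
      double v = vE[j];
      v += dt / tauE * (v * v + Ith + Ie[j]);
      if (v >= vb) { spikesE.push_back(j); v = -vb; }
      vE[j] = v;
    }
    for (int j = 0; j < nI; ++j) {
      double v = vI[j];
      v += dt / tauI * (v * v + Ith + Ii[j]);
      if (v >= vb) { spikesI.push_back(j); v = -vb; }
      vI[j] = v;
    }
    // synaptic pulse delivery (arrives at the spike step)
    if (!spikesE.empty()) {
      double kickI = 2.0 * gIE * spikesE.size();
      for (int j = 0; j < nI; ++j) vI[j] += kickI;
      for (size_t q = 0; q < spikesE.size(); ++q) {
        int l = spikesE[q];
        const std::vector<int> &post = adjEE[l];
        for (size_t k = 0; k < post.size(); ++k) {
          vE[post[k]] += 2.0 * gEE;
          xA[post[k]] += 2.0 * tauE * gEE / tauRA;
        }
        spk_t.push_back(t); spk_id.push_back(l + 1);
      }
    }
    if (!spikesI.empty()) {
      double kickE = 2.0 * gEI * spikesI.size();
      for (int j = 0; j < nE; ++j) vE[j] -= kickE;
      xG += 2.0 * tauE * gEI / tauRG * spikesI.size();
      for (size_t q = 0; q < spikesI.size(); ++q) {
        int l = spikesI[q];
        const std::vector<int> &post = adjII[l];
        for (size_t k = 0; k < post.size(); ++k) vI[post[k]] -= 2.0 * gII;
        spk_t.push_back(t); spk_id.push_back(nE + l + 1);
      }
    }
    // synaptic current kinetics and LFP accumulation
    double lfp_now = 0.0;
    for (int j = 0; j < nE; ++j) {
      IA[j] += dt / tauDA * (-IA[j] + xA[j]);
      xA[j] += dt / tauRA * (-xA[j]);
      lfp_now += std::fabs(IA[j]);
    }
    IG += dt / tauDG * (-IG + xG);
    xG += dt / tauRG * (-xG);
    lfp_now += nE * std::fabs(IG);

    if (t >= transient_ms) {
      int bin = (int)((t - transient_ms) / record_dt);
      if (bin >= 0 && bin < nrec) {
        double mv = 0.0;
        for (int j = 0; j < nI; ++j) mv += vI[j];
        lfp_acc[bin] += lfp_now;
        vI_acc[bin] += mv / nI;
        rec_n[bin] += 1;
      }
    }
    if (!std::isfinite(vE[0])) overflow = true;
    if (s % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  if (overflow) stop("membrane potential overflow: reduce dt or coupling");

  for (int b = 0; b < nrec; ++b) {
    int m = rec_n[b] > 0 ? rec_n[b] : 1;
    lfp[b] = lfp_acc[b] / m;
    vImean[b] = vI_acc[b] / m;
    double tb = transient_ms + (b + 0.5) * record_dt;
    double ph = twopi * nu * tb / 1000.0;
    theta_phase[b] = ph - twopi * std::floor(ph / twopi);
  }
  return List::create(_["spike_time"] = wrap(spk_t),
                      _["spike_neuron"] = wrap(spk_id),
                      _["lfp"] = lfp,
                      _["vI_mean"] = vImean,
                      _["theta_phase"] = theta_phase);
}
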