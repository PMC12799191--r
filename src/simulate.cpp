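// Clock-driven integrator for the flexor reflex-loop spiking network.
//
// All quantities use a consistent unit system: mV, nS, pF, pA, ms.
// With these units dV/dt [mV/ms] = (nS * mV + pA) / pF holds without
// conversion factors. Forward Euler at a fixed step (default 0.05 ms).
//
// Neuron kinds:
//   0 = conductance LIF        dV = (gL(EL - V) + Isyn + I)/C
//   1 = AdEx                   adds gL*DeltaV*exp((V - Vth)/DeltaV) - w
//   2 = exponential LIF        AdEx with w frozen at 0
// LIF spikes at Vth; AdEx/expLIF spike at the numerical cutoff Vcut.
//
// Synapses: single-exponential conductance for excitation (tau_exc),
// peak-normalised bi-exponential ("alpha") for inhibition (tau rise/decay).
// Presynaptic gating: edges of kind 2 deposit a GABA-spillover quantum on
// the target's local concentration C_gaba; excitatory deliveries flagged
// "gated" are scaled by the target's release factor gamma, which relaxes
// toward clamp(1 - lambda * C_gaba, 0, 1) with time constant tau_gamma.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
List cpp_simulate(List neurons, List edges, List drive, List es,
                  NumericMatrix inj, List gatepar, List recpar,
                  double T_ms, double dt_ms,
                  int seed_noise, int seed_drive, int seed_es) {
  // --- neuron parameter vectors -------------------------------------------
  IntegerVector kind   = neurons["kind"];
  NumericVector C      = neurons["C"];
  NumericVector gL     = neurons["gL"];
  NumericVector EL     = neurons["EL"];
  NumericVector Vth    = neurons["Vth"];
  NumericVector Vreset = neurons["Vreset"];
  NumericVector DeltaV = neurons["DeltaV"];
  NumericVector a_w    = neurons["a"];
  NumericVector tauw   = neurons["tauw"];
  NumericVector b_w    = neurons["b"];
  NumericVector tref   = neurons["tref"];
  NumericVector Vcut   = neurons["Vcut"];
  NumericVector nsd    = neurons["noise_sd"];
  IntegerVector nospk  = neurons["no_spike"];
  const int n = kind.size();

  const double tau_exc = as<double>(neurons["tau_exc"]);
  const double tau_ir  = as<double>(neurons["tau_inh_rise"]);
  const double tau_id  = as<double>(neurons["tau_inh_decay"]);
  const double E_exc   = as<double>(neurons["E_exc"]);
  const double E_inh   = as<double>(neurons["E_inh"]);

  // peak-normalisation of the bi-exponential inhibitory kernel
  const double tpk   = std::log(tau_id / tau_ir) * tau_id * tau_ir / (tau_id - tau_ir);
  const double anorm = 1.0 / (std::exp(-tpk / tau_id) - std::exp(-tpk / tau_ir));

  // --- edges in CSR form ---------------------------------------------------
  IntegerVector eptr   = edges["eptr"];    // length n+1, 0-based offsets
  IntegerVector etgt   = edges["tgt"];
  NumericVector ew     = edges["w"];
  IntegerVector ekind  = edges["kind"];    // 0 exc, 1 inh, 2 gate
  IntegerVector edel   = edges["delay_steps"];
  IntegerVector egated = edges["gated"];

  // --- afferent Poisson drive ----------------------------------------------
  IntegerVector dgid = drive["gids"];      // 0-based neuron ids
  NumericMatrix drate = drive["rates"];    // nsamp x ndrive, Hz
  double dfs = as<double>(drive["fs"]);    // Hz
  NumericVector dg = drive["g"];           // nS per event, per drive line
  const int ndrive = dgid.size();
  const int nsamp  = drate.nrow();

  // --- electrical stimulation ----------------------------------------------
  IntegerVector es_gid = es["gids"];       // targeted neurons (0-based)
  IntegerVector es_src = es["src"];        // source index per target
  int es_nsrc   = as<int>(es["n_src"]);
  double es_f   = as<double>(es["freq"]);  // Hz
  NumericVector es_amp = es["I_amp"];      // pA per target while pulse active
  int es_pw     = as<int>(es["pw_steps"]);
  const int nes = es_gid.size();

  // --- gate parameters ------------------------------------------------------
  const double lambda = as<double>(gatepar["lambda"]);
  const double tau_g  = as<double>(gatepar["tau_gamma"]);

  // --- recording ------------------------------------------------------------
  IntegerVector rec_v = recpar["v_gids"];
  IntegerVector rec_g = recpar["g_gids"];
  int rec_every = as<int>(recpar["every"]);

  const int nsteps = (int)std::llround(T_ms / dt_ms);
  const double dt_s = dt_ms * 1e-3;

  // ring buffers for delayed deliveries
  int D = 1;
  for (int e = 0; e < etgt.size(); ++e) D = std::max(D, edel[e] + 1);
  std::vector<double> bufE((size_t)D * n, 0.0), bufEg((size_t)D * n, 0.0),
                      bufI((size_t)D * n, 0.0), bufG((size_t)D * n, 0.0);

  // state
  std::vector<double> V(n), w(n, 0.0), gE(n, 0.0), hR(n, 0.0), hD(n, 0.0),
                      gamma(n, 1.0), Cg(n, 0.0), Iinj(n, 0.0);
  std::vector<int> refr(n, -1), pulse_until(n, -1);
  std::vector<double> esI(n, 0.0);
  for (int j = 0; j < nes; ++j) esI[es_gid[j]] = es_amp[j];
  for (int i = 0; i < n; ++i) V[i] = EL[i];

  const double decE = std::exp(-dt_ms / tau_exc);
  const double decR = std::exp(-dt_ms / tau_ir);
  const double decD = std::exp(-dt_ms / tau_id);
  const double decG = std::exp(-dt_ms / tau_g);

  std::mt19937_64 rng_noise(seed_noise), rng_drive(seed_drive), rng_es(seed_es);
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  std::vector<int> spk_i;
  std::vector<double> spk_t;
  spk_i.reserve(1 << 16);
  spk_t.reserve(1 << 16);

  const int nrecv = rec_v.size(), nrecg = rec_g.size();
  const int nrect = (rec_every > 0) ? ((nsteps + rec_every - 1) / rec_every) : 0;
  NumericMatrix Vrec(nrecv > 0 ? nrect : 0, nrecv);
  NumericMatrix Grec(nrecg > 0 ? nrect : 0, nrecg);
  NumericVector Trec(nrect);
  int rrow = 0;

  const int ninj = inj.nrow();

  for (int k = 0; k < nsteps; ++k) {
    const double t = k * dt_ms;
    const int slot = k % D;
    double *bE = &bufE[(size_t)slot * n], *bEg = &bufEg[(size_t)slot * n],
           *bI = &bufI[(size_t)slot * n], *bG = &bufG[(size_t)slot * n];

    // 2. afferent Poisson events (rate series sampled at dfs)
    if (ndrive > 0) {
      int s = (int)(t * 1e-3 * dfs);
      if (s >= nsamp) s = nsamp - 1;
      for (int j = 0; j < ndrive; ++j) {
        double p = drate(s, j) * dt_s;
        if (p > 0.0 && runif01(rng_drive) < p) gE[dgid[j]] += dg[j];
      }
    }

    // 3. ES Poisson sources -> rectangular current pulses on their fibres
    if (nes > 0 && es_f > 0.0) {
      for (int src = 0; src < es_nsrc; ++src) {
        if (runif01(rng_es) < es_f * dt_s) {
          for (int j = 0; j < nes; ++j)
            if (es_src[j] == src) pulse_until[es_gid[j]] = k + es_pw;
        }
      }
    }

    // 4. programmed current injections
    if (ninj > 0) {
      std::fill(Iinj.begin(), Iinj.end(), 0.0);
      for (int r = 0; r < ninj; ++r)
        if (t >= inj(r, 1) && t < inj(r, 2)) Iinj[(int)inj(r, 0)] += inj(r, 3);
    }

    // 5. deliver due events, integrate, decay, and update the gate in one
    // pass (cross-neuron interaction happens only through spike buffers,
    // which are written at least one step ahead)
    for (int i = 0; i < n; ++i) {
      if (bE[i] != 0.0)  { gE[i] += bE[i];  bE[i] = 0.0; }
      if (bEg[i] != 0.0) { gE[i] += gamma[i] * bEg[i]; bEg[i] = 0.0; }
      if (bI[i] != 0.0)  { double q = anorm * bI[i]; hR[i] += q; hD[i] += q; bI[i] = 0.0; }
      if (bG[i] != 0.0)  { Cg[i] += bG[i]; bG[i] = 0.0; }
      double Vi = V[i];
      // adaptation current evolves even through the refractory hold
      if (kind[i] == 1) w[i] += dt_ms * (a_w[i] * (Vi - EL[i]) - w[i]) / tauw[i];

      if (k < refr[i]) {
        V[i] = Vreset[i];
        gE[i] *= decE; hR[i] *= decR; hD[i] *= decD;
        Cg[i] *= decG;
        gamma[i] += dt_ms / tau_g * (clamp01(1.0 - lambda * Cg[i]) - gamma[i]);
        continue;
      }

      double Isyn = gE[i] * (E_exc - Vi) + (hD[i] - hR[i]) * (E_inh - Vi);
      double I = Isyn;
      if (ninj > 0) I += Iinj[i];
      if (nes > 0 && k < pulse_until[i]) I += esI[i];
      if (nsd[i] > 0.0) I += nsd[i] * rnorm01(rng_noise);

      double dV;
      if (kind[i] == 0) {
        dV = (gL[i] * (EL[i] - Vi) + I) / C[i];
      } else {
        double ex = 0.0;
        if (!nospk[i]) {
          double arg = (Vi - Vth[i]) / DeltaV[i];
          if (arg > 30.0) arg = 30.0;  // overflow guard; spike fires at Vcut anyway
          ex = gL[i] * DeltaV[i] * std::exp(arg);
        }
        double wi = (kind[i] == 1) ? w[i] : 0.0;
        dV = (gL[i] * (EL[i] - Vi) + ex + I - wi) / C[i];
      }
      Vi += dt_ms * dV;

      double thr = (kind[i] == 0) ? Vth[i] : Vcut[i];
      if (!nospk[i] && Vi >= thr) {
        spk_i.push_back(i);
        spk_t.push_back(t + dt_ms);
        Vi = Vreset[i];
        refr[i] = k + 1 + (int)std::llround(tref[i] / dt_ms);
        if (kind[i] == 1) w[i] += b_w[i];
        // propagate
        for (int e = eptr[i]; e < eptr[i + 1]; ++e) {
          int s2 = (k + edel[e]) % D;
          double *row;
          if (ekind[e] == 0)      row = egated[e] ? &bufEg[(size_t)s2 * n] : &bufE[(size_t)s2 * n];
          else if (ekind[e] == 1) row = &bufI[(size_t)s2 * n];
          else                    row = &bufG[(size_t)s2 * n];
          row[etgt[e]] += ew[e];
        }
      }
      V[i] = Vi;
      if (!std::isfinite(Vi))
        stop("non-finite membrane potential at neuron %d, t = %f ms", i + 1, t);
      gE[i] *= decE; hR[i] *= decR; hD[i] *= decD;
      Cg[i] *= decG;
      gamma[i] += dt_ms / tau_g * (clamp01(1.0 - lambda * Cg[i]) - gamma[i]);
    }

    // 7. record
    if (rec_every > 0 && (k % rec_every) == 0 && rrow < nrect) {
      Trec[rrow] = t;
      for (int j = 0; j < nrecv; ++j) Vrec(rrow, j) = V[rec_v[j]];
      for (int j = 0; j < nrecg; ++j) Grec(rrow, j) = gamma[rec_g[j]];
      ++rrow;
    }
  }

  return List::create(
    _["spike_gid"] = IntegerVector(spk_i.begin(), spk_i.end()),
    _["spike_t"]   = NumericVector(spk_t.begin(), spk_t.end()),
    _["t_rec"]     = Trec, _["V"] = Vrec, _["gamma"] = Grec,
    _["V_end"]     = NumericVector(V.begin(), V.end()),
    _["gamma_end"] = NumericVector(gamma.begin(), gamma.end()),
    _["Cg_end"]    = NumericVector(Cg.begin(), Cg.end()));
}
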