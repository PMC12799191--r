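---
title: "The ankle-flexor reflex-loop model: assumptions, calibration, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ankle-flexor reflex-loop model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinalsnn)
```

## The model

`spinalsnn` simulates the mono- and di-synaptic stretch-reflex loop of the
rodent tibialis anterior (TA, ankle flexor) as a clock-driven spiking
network. Muscle-spindle afferents of the flexor and its antagonist
(gastrocnemius medialis, GM) encode gait kinematics as firing rates:

* primary (Ia) fibres: `rate = 50 + 2 x + 4.3 sign(v) |v|^0.6 + K * 50 * EMG`,
* secondary (II) fibres: `rate = 80 + 13.5 x + K * 20 * EMG`,

where `x` is spindle stretch, `v` its velocity, `EMG` the normalised
envelope of the muscle's activity, and `K` a muscle-specific unloading gain
that is zero at full weight bearing. Rates are clipped at zero — the
equations can go negative under strong unloading, and a Poisson intensity
cannot. Each of the 60 axons per fibre class relays an independent
inhomogeneous Poisson train through a leaky integrate-and-fire (LIF) cable
whose capacitance follows from its radius (Ia 9 ± 0.2 µm, II 4.4 ± 0.5 µm,
specific capacitance 1 µF/cm², length 1 mm). The drive weight is large
enough that every drive event is suprathreshold, so an axon reproduces its
commanded rate up to refractory dead-time loss (1.6 ms), the same
"tuned relay" behaviour the loop's afferent pathway is built on.

Downstream, four populations close the loop:

* **IaIN** (196 per muscle side): conductance-based LIF reciprocal
  inhibitory interneurons; the extensor-side pool inhibits TA motoneurons.
* **GABA** (196): adaptive exponential (AdEx) interneurons driven by
  extensor Ia afferents; their spikes do not inhibit postsynaptically but
  load a spillover concentration `C` at flexor-motoneuron terminals.
* **V2a** (196): AdEx excitatory interneurons driven by flexor afferents,
  providing tonic drive to motoneurons.
* **MN** (169): exponential-LIF TA motoneurons (AdEx with the adaptation
  current frozen at zero).

Presynaptic inhibition is a multiplicative release factor `gamma` on every
excitatory synapse onto the motoneuron pool, relaxing toward
`clamp(1 - 0.4 * C, 0, 1)` with a 20 ms time constant. Each arriving GABA
spike adds a quantum `dC` to its target's concentration, which decays with
the same time constant. Synapses are conductance-based: single-exponential
excitation (0.25 ms, reversal 0 mV) and peak-normalised bi-exponential
inhibition (2 ms rise / 4.5 ms decay, reversal −75 mV). Axonal synapses
carry delays drawn from Normal(2, 0.3) ms truncated at 0.1 ms. Integration
is forward Euler at 50 µs.

Seven conditions toggle four mechanisms: injury (`SCI`, 1.6-fold GABA-MN
gate pairing), body-weight support (`BWS`, afferent unloading gains
`K_GM = -0.6`, `K_TA = -0.122`; modelled on the injured cord), epidural-style
electrical stimulation (`ES`, Poisson pulse sources at 40 Hz / 10 mV /
0.2 ms, each driving three non-overlapping fibres), and a serotonergic
surrogate (leak conductance of MN and V2a reduced 40% in SCI conditions,
15% in BWS conditions).

## Decisions the design left open

**Spike-triggered adaptation.** The AdEx equations as used here have no
spike-triggered adaptation increment (`b = 0`); only subthreshold
adaptation (`a`, `tau_w`) acts. `b` is a column in the parameter table and
can be overridden.

**Numerical spike cutoff.** Exponential models detect spikes at
`V_cut = V_th + 5 * DeltaV`, which stops the exponential blow-up
deterministically; for the motoneuron (`DeltaV = 0.05 mV`) this is within
0.25 mV of the nominal threshold, i.e. effectively a hard threshold.

**Refractory periods.** Only the axons have a literature value (1.6 ms);
interneurons and motoneurons default to the same value for uniformity and
accept overrides.

**Spillover dynamics.** The local GABA concentration is a per-motoneuron
leaky accumulator: spikes add a quantum `dC` (default 0.195) and the
concentration decays with the gate time constant. The quantum is the one
deliberately free constant of the loop. It was calibrated once, against the
network's own validation bands (below), not per condition.

**Gate granularity.** One release factor per motoneuron gates all of its
excitatory synapses (afferent and V2a alike), matching a population-level
reading of terminal inhibition.

**Injury pairing.** The 1.6-fold pair count is reached by widening the
index window from 4 to 6 (1844 pairs) and topping up with 39 pairs sampled
at index distance 6, preserving spatial locality; sampling is
deterministic given the wiring seed.

**Settling cycle.** Runs start from rest with `gamma = 1`, so the first
~150 ms carry an initialisation transient in which even the injured loop
fires briskly. One settling gait cycle is simulated and discarded
(`settle_steps = 1`) before the analysed window; without it the transient
dominates the near-silent injured condition.

## What the synthetic gait emulates — and what it does not

The generator produces periodic stretch/velocity/EMG profiles at 200 Hz
with the stance/swing split at 65% of the cycle, the extensor envelope
active in stance, the flexor envelope in swing, and stretch in anti-phase
with each muscle's own envelope. Cycle duration defaults to 0.7 s, the
midpoint of the validated rodent burst-period band (0.5–0.9 s). Envelopes
are plateau-clipped raised cosines with ~3% cycle-to-cycle amplitude
jitter.

Waveform amplitudes are package calibration constants:

* TA stretch = tonic base 4 + raised-cosine bump 9 centred mid-stance;
* GM stretch = bump 0.5 (quasi-tonic), base 0;
* spillover quantum `dC = 0.195`.

Two structural facts drove this calibration. First, the reciprocal IaIN
pair is winner-take-all at the given synaptic strengths: the inhibitory
reversal equals the resting potential, so a suppressed pool cannot
depolarise enough to fight back, and whichever side wins stays the winner.
Functional flexor output requires the flexor-side pool to win and hold;
the tonic TA stretch base keeps its group-II drive above rheobase through
the shortening-phase velocity dip of the Ia equation, and the weak GM
modulation denies the extensor pool a phasic edge. Second, the release
factor must sit near its clamp cliff: with the quantum at 0.195 the
baseline loop runs at `gamma ≈ 0.4` and the 1.6-fold injury pairing pushes
it to near zero, which is what produces the ~50-fold collapse of
motoneuron output rather than a proportional dip.

With these defaults the simulator reproduces, across seeds: baseline
in-burst motoneuron rates within 100–500 Hz and burst periods within
0.5–0.9 s (4 ms analysis windows); an EPSP photostimulation conditioning
ratio of ~0.65; a Baseline/SCI rate ratio of a few tens; and a
~3-fold increase in the coefficient of variation under injury.

What passing these bands does **not** show: the generator's waveforms are
idealised (no load-dependent extensor afferent modulation during stance,
no inter-muscle timing variability, no speed changes), so condition means
should not be read as quantitative predictions for real treadmill data —
the contrasts between conditions, which is what the analysis stack tests,
are the meaningful output.

## Protocols

* **F-I characterisation** (`fi_curve`): 200 ms pulses, 10–3160 pA,
  noise-free, on any population model.
* **Photostimulation** (`photostim_epsp_ratio`): 15 threshold pulses
  (1 ms, 50 Hz) into the GABA pool beginning 45 ms before a single
  afferent test volley at 1.1× threshold; motoneuron spiking disabled;
  the conditioned/control EPSP peak ratio quantifies terminal inhibition.
  Thresholds (GABA rheobase, afferent volley threshold) are found by
  bisection per protocol run.
* **Recruitment sweep** (`recruitment_sweep`): synthetic logistic
  recruitment thresholds (labelled synthetic; Ia before II before direct
  MN) stand in for field-model data; each amplitude recruits the fibres at
  or below it, the evoked response is converted to synthetic EMG, and
  early/middle/late windows are read at 1/4/7 ms latency.
* **ES sweeps**: amplitude {5,...,50} mV and frequency {20,...,100} Hz.

## The seed-equivalence model

Per-step mean firing rates `y` are modelled with step time rescaled to
[0, 1] and a cubic B-spline basis with 4 equidistant interior knots
(basis dimension 8, a partition of unity; the constant direction is
carried by the intercept, so spline coefficients are constrained to the
orthogonal complement — the usual sum-to-zero identifiability constraint):

`y_i = a_c + B(t_i)' beta_c + a_s + B(t_i)' beta_s + eps`,

with condition-level intercept and trajectory, seed effects nested in
condition, and priors `a_c ~ N(0,10)`, `beta_c ~ N(0,2)`,
`sigma ~ HalfNormal(2)`, seed-effect scales `tau ~ HalfNormal(1)`.
Equivalence across seeds is declared when
`P(tau_int < 5 Hz) >= 0.9` and `P(tau_dyn < max(5, 0.05 max fitted rate))
>= 0.9`, and the fit passes its gates: no divergences, split R-hat < 1.05,
BFMI > 0.9 per chain, posterior-predictive R² > 0.7.

Inference uses the package's own No-U-Turn sampler (multinomial tree
doubling, dual-averaging step size, jittered steps, diagonal or dense
mass-matrix adaptation; 4 chains, 1000 warmup + 1000 draws at target
acceptance 0.9 by default). Two formulations are provided and
cross-checked against each other:

* `method = "marginal"` (default): the Gaussian seed effects are
  integrated out exactly, leaving ~a dozen parameters with per-seed
  covariance `sigma² I + tau_int² J + tau_dyn² B B'`. This removes the
  latent funnel entirely — scale parameters are sampled as signed
  Gaussian auxiliaries (`tau = |eta|`), which avoids the heavy log-scale
  tail when a scale is consistent with zero.
* `method = "latent"`: the non-centred parameterisation sampled in full.

Convergence diagnostics are computed on identified quantities (the signed
auxiliaries carry a sign symmetry, so R-hat uses `|eta|` and the products
`eta * z`).

The parameter-recovery study behind the package's tests uses 16 seeds ×
8 steps with a trajectory on the scale the priors express; at that size
the zero-effect case passes every fit gate and injected 20 Hz seed
intercepts are rejected decisively.

## Frequentist stack

Shapiro–Wilk gates paired t vs Wilcoxon signed-rank; equivalence uses two
one-sided tests at ±15 Hz (optionally on `log1p` scale); within-timestep
contrasts use sign-flip permutation of the paired differences within each
seed, 2000 repetitions. Pairwise p-values are reported raw (a Holm option
exists in `stats::p.adjust` for users who want it); aggregation follows
two modes — across-seed means per step (n = steps) for condition
contrasts, and per-seed mean absolute inter-step differences (n = seeds)
for step-dynamics metrics. Outliers are removed at |z| > 3.

## Problem sizes used by the packaged analyses

The packaged tests and the acceptance script run: single-seed 8-step runs
for burst validation; 8 matched seeds per condition for the injury
contrast; 8 seeds for the photostimulation ratio; 2-step runs for the ES
sweeps; and 16-seed recovery datasets for the equivalence model. These
sizes give stable statistics for every reported contrast while keeping a
full re-run on a single CPU comfortable; the full 32-seed study protocol
is available through `run_seed_bank`.

## Known limitations

* The loop is ipsilateral and feedforward: no commissural circuitry, no
  closed-loop musculoskeletal feedback, no plastic adaptation.
* The serotonergic surrogate is a single conductance change; it cannot
  express plateau potentials or dose dynamics.
* ES is a membrane-potential pulse on afferent axons; there is no
  electrode/tissue field model, so amplitudes are nominal depolarisations
  rather than electrode currents.
* The motoneuron parameter set has a rheobase of ~674 pA; published
  single-cell protocols quoted at 670 pA sit marginally below it, so
  pulse-response contrasts are probed just above the model's own rheobase.
* With the printed synaptic strengths the reciprocal IaIN pair is
  bistable; the gait calibration deliberately keeps the flexor side
  dominant, which is a modelling commitment, not an emergent prediction.
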