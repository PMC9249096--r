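---
title: "Cholinergic modulation of scale-free spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cholinergic modulation of scale-free spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(achnet)
```

## The scientific question

Acetylcholine (ACh) tone varies systematically across behavioral states:
high during wake and REM sleep, low during slow-wave sleep. Muscarinic ACh
receptors suppress the slow, non-inactivating M-type potassium current, so
the maximal conductance of that current, `g_Ks`, serves as an *inverse*
proxy for ACh level. `achnet` simulates networks of conductance-based
neurons in which `g_Ks` is the single state variable distinguishing
wake-like (`g_Ks = 0` mS/cm²) from sleep-like (`g_Ks = 1.5` mS/cm²)
dynamics, embedded in directed scale-free topologies whose hub bias is
tunable, and asks how the ACh state reshapes synchrony, spike ordering, and
spike-timing-dependent plasticity (STDP)-driven rewiring.

## The neuron model

Each cell follows a single-compartment Hodgkin–Huxley-type membrane
equation with four currents (transient sodium with instantaneous
activation, delayed-rectifier potassium, M-type potassium gated by `z`,
and leak):

$$C\dot V = -g_{Na} m_\infty^3(V)\,h\,(V-E_{Na}) - g_{Kdr}\,n^4\,(V-E_K)
 - g_{Ks}\,z\,(V-E_K) - g_L\,(V-E_L) + I_{drive} + I_{noise} - I_{syn}$$

with `C` = 1 µF/cm², `g_Na` = 24, `g_Kdr` = 3, `g_L` = 0.02 mS/cm²,
`E_Na` = 55, `E_K` = −90, `E_L` = −60 mV, and first-order gate kinetics
for `h`, `n`, `z` (`tau_z` = 75 ms). The gating sigmoids are centred at
−30 (`m`, slope 9.5 mV), −53 (`h`), −30 (`n`), and −39 mV (`z`); see
`gating_functions()`.

One typeset ambiguity deserves a note: the published rendering of the
sodium-activation slope is corrupted and could be read as 0.5 mV. We
adopted 9.5 mV, the value of the reduced cortical-neuron lineage this
model descends from, after checking both readings numerically: only 9.5 mV
reproduces the defining phenomenology of the model — a continuous (Type I)
frequency–current (f-I) onset with a strictly positive phase-response
curve (PRC) at `g_Ks = 0`, and a discontinuous (Type II) onset with a
biphasic PRC and flat suprathreshold f-I at `g_Ks = 1.5`. With slope
0.5 mV both ACh states show a pathological near-discontinuous onset around
7.5 µA/cm², which contradicts the model's own characterization.

A consequence worth knowing: at `g_Ks = 0` the cell has *no* stable
subthreshold fixed point at zero applied current (rheobase is slightly
negative, ≈ −0.1 µA/cm²). The "highest subthreshold applied current" that
the protocols use as the per-`g_Ks` drive (`select_drive()`) is therefore
a small hyperpolarizing current in the wake state and ≈ +1.16 µA/cm² at
`g_Ks = 1.5`. `select_drive()` defines "subthreshold" by steady-state
silence (second half of a 2-s run): Type II cells can fire a single onset
spike below rheobase, which would otherwise make the definition
ill-posed.

## Numerics

Integration is classical RK4 at `dt = 0.1` ms, with drive, noise, and
synaptic currents held constant across the four substages of a step
(inputs are defined per step; this also decouples the update across
neurons within a step). Gates are clipped to [0, 1] after each step —
a guard against the O(dt⁴) overshoot of the polynomial update. Spikes are
upward crossings of 0 mV, assigned to the step in which the crossing
completes; no sub-step interpolation is used, so all spike times are
quantized to `dt`. Halving `dt` changes steady-state interspike intervals
by well under 0.1 ms (the absolute spike-time offset carries the quantized
onset transient and can reach ~2–3 steps over 2 s).

The per-step network loop is compiled (Rcpp). Synaptic kernels are not
resummed event-by-event inside the integrator: the double-exponential
kernel is the difference of two exponentially decaying traces that jump by
1 at each presynaptic spike, which is the exact (infinite-window) sum. The
event-driven form with an explicit cutoff (`synaptic_current()`, cutoff
10·τ_d, truncation < 5·10⁻⁵ of peak) is kept as the re-analysis and
testing surface, and the pure-R stepper `rk4_step()` is retained as an
independent oracle: the compiled path must agree with it to 10⁻¹² over
1000 steps, and the compiled STDP path must reproduce an event-by-event R
replay of the same spike history exactly.

Initial conditions follow the study design: V uniform on [−70, 0] mV,
gates at 0 except `h(0) = 1`. Cells initialized near threshold typically
fire one onset spike; every pairwise analysis therefore uses only the
second half of its segment.

## Network construction

`build_scale_free()` grows an undirected graph on `n = 250` nodes by
executing a linearized-chord-diagram style preferential-attachment pass 15
times over the same node set, accumulating degrees and the union of edges
(no self- or multi-edges). The only genuinely open design point is what to
do when an entering node is already connected to every earlier node (which
happens for early nodes in later passes). Skipping such attachments loses
exactly $\sum_{m=1}^{14}(15-m) = 105$ edges and drags the mean in-degree
to 14.52, 3% below the design target of 15; we instead fall back to a
degree-weighted draw over all remaining non-neighbours, which preserves
the per-pass budget exactly: 15·249 = 3735 edges, mean in-degree 14.94.

`orient_edges()` turns each undirected edge into exactly one directed
synapse: with probability `p_in` the edge points into its higher-degree
endpoint. `p_in` ∈ {0.1, 0.3, 0.5, 0.7, 0.9} spans "strong hub outgoing"
to "strong hub incoming". Hubs are the top 10% of excitatory cells by
total degree (25 cells at n = 250), ties broken by lower index. Mixed E-I
networks keep 225 excitatory cells scale-free and wire each of the 25
inhibitory cells with K = 15 random excitatory inputs and K = 15 random
outputs (conductance 0.01 mS/cm²); K is not stated in the study design and
was matched once to the network's mean degree.

## Synapses and plasticity

Presynaptic spikes at `t_k` contribute
`w_ij (e^{-(t-t_k)/0.5} − e^{-(t-t_k)/0.2}) (V_i − E_syn)` µA/cm², with
`E_syn` 0 mV (excitatory) or −75 mV (inhibitory); every excitatory synapse
starts at `w₀ = g_syn = 0.04` mS/cm² unless swept. The STDP rule is fully
asymmetric with equal magnitudes: each (pre, post) spike pair with
`0 < |Δt| ≤ 40` ms contributes `±A_L e^{−|Δt|/10 ms}` (pre-before-post
potentiates), all-to-all within the window, nothing at `Δt = 0`. Weights
are clipped to [0, 2w₀] and synapses absent at initialization are never
created; only synapses with excitatory presynaptic cells are plastic.
`A_L` defaults to 0.002 mS/cm² (the model description's value; the
source's parameter table prints 0.0002, and the parameter is exposed for
that reading — at 0.0002 all reorganization magnitudes scale down roughly
tenfold and no longer reach the reported regional changes).

Updates are applied at spike events within the integration step, after the
voltage update: potentiation for all neurons spiking this step, then
depression, each clipped immediately. At `dt = 0.1` ms the within-step
order is unobservable.

## Analysis measures

All pairwise measures use the second half of each segment and mask neurons
with fewer than 2 spikes there.

- **Mean phase coherence** (`mean_phase_coherence()`): spikes of train j
  are assigned phases within the enclosing interspike intervals of
  reference train i; the statistic is the resultant length. Entry (i, j)
  of `mpc_matrix()` uses i as reference; network averages are over ordered
  pairs.
- **Zero-lag cross-correlation** (`cross_correlation()`): trains binned at
  `dt`, convolved with a unit-area Gaussian (σ = 1 ms, truncated at ±5σ),
  mean-subtracted, normalized inner product.
- **AMD and its Z-score** (`amd()`, `amd_zscore()`): mean distance from
  each spike of i to the most recent *preceding* spike of j. The
  preceding-spike reading (rather than nearest-event) is forced by the
  analytic null the study supplies: spikes placed uniformly on j's
  interval structure have preceding-distance mean μ₁ = ΣL²/(2T) and
  variance μ₂ − μ₁² with μ₂ = ΣL³/(3T) — the nearest-event expectation
  would be ΣL²/(4T) instead. For the same reason the null moments are
  computed from the ISIs of the train distances are measured *to* (the
  reference j), and the Z-score uses the standard error of the mean:
  `Z_ij = (AMD_ij − μ₁ⱼ)/(σⱼ/√N_i)` over the N_i usable spikes of i, with
  Z < −2 flagging i locked shortly after j. The √N factor is not
  optional: a preceding-distance density is always non-increasing, which
  bounds σ/μ₁ ≥ 1/√3, so the single-distance normalization could never
  leave (−√3, √3) and the ±2 threshold would be unreachable for any spike
  train. The asymmetry matrix `Z − Zᵀ` is exactly antisymmetric;
  region averages index it (post, pre) like the weight matrix, so a
  *negative* hub→non-hub asymmetry means non-hub activity is locked just
  after hub activity, i.e. hubs lead.
- **Region-resolved reorganization** (`region_delta()`): summed weight
  change per region (within hub, within non-hub, hub→non-hub,
  non-hub→hub), normalized by (synapse count × w₀).
- **LFP proxy** (`lfp_spectrum()`): summed excitatory voltage, z-scored,
  FFT, dominant frequency over 1–100 Hz.

## Protocols and ensemble design

Every reported quantity is an ensemble statistic: each condition is
repeated `n_trials = 10` times with a fresh topology, fresh initial
conditions and fresh noise (trial k uses `seed + k − 1`), and trial means
with standard errors are reported. The drivers are `gks_sweep()`,
`robustness_sweeps()` (g_syn ∈ {0.02…0.08} mS/cm²; noise amplitudes
1.5–4 µA/cm² at 0.1% initiation probability), `ei_comparison()`,
`hub_removal_experiment()` (2 s intact + 2 s with hub rows/columns zeroed,
state carried over), `stdp_reorganization()` (3 s plastic runs), and
`wake_sleep_wake()` (3 s wake / 3 s sleep with STDP / 3 s wake; rates over
the last 2 s of each wake segment).

For the wake–sleep–wake regression the study leaves the pooling ambiguous.
We fit per trial (250 per-neuron points) *and* pool across trials after
aligning neurons by descending-degree rank — neurons are not identifiable
across trials (each trial has its own topology), and degree rank is the
covariate that determines a neuron's role, so the rank-averaged points are
the natural pooled dataset. The pooled fit is the headline slope/R².

## What the defaults reproduce, and what they do not

With the defaults above the package reproduces, as ensemble trends: the
synchronization transition (MPC ≈ 0.13 → ≈ 0.9, CC ≈ 0 → ≈ 0.2 from
`g_Ks` 0 → 1.5 at p_in = 0.5), the drastic rate reduction and
homogenization at low ACh, hub-led temporal ordering at high `g_Ks`,
coherence loss after hub removal in the synchronized state only, and the
sign structure of STDP reorganization (hub→non-hub potentiation with
non-hub→hub depression at low ACh; within-hub potentiation at high ACh).

Three quantitative points fall short of the reported magnitudes and are
left as honest discrepancies rather than tuned. The network oscillation at
`g_Ks = 1.5` sits at ~10–11 Hz (at or above the upper edge of the reported
theta band). The wake–sleep–wake regression slope, measured over 10 trials
per configuration, is −0.45 / −0.24 / −0.09 for strong-hub-out / balanced /
strong-hub-in with R² 0.63–0.75 (reported: all in [−0.6, −0.5] with
R² > 0.98): robustly negative and linear, but weaker and — unlike the
report — strongly dependent on the hub orientation. And the hub→non-hub
reorganization at `g_Ks = 1.5`, p_in = 0.7 reaches +24.9% ± 1.1 against
the reported "about 35%" (all four regional signs match). These
discrepancies plausibly share a cause: the burst timing statistics of the
low-ACh state control the effective STDP lag distribution, and a faster,
tighter oscillation yields smaller net regional weight changes and weaker
rate renormalization.

The synthetic conditions also idealize real tissue in ways passing tests
cannot speak to: no conduction delays, point neurons, a single global ACh
level, pulse noise rather than structured afferent input, and a hub
definition purely by degree.

## Problem sizes used by the test suite

Structural unit tests run on scaled-down instances (20–120 neurons,
0.5–1.2 s). The ensemble claims are tested at the full study conditions —
250 neurons, 15 growth passes, 10 trials per condition, 2–9 s per trial —
which makes the acceptance portion of the suite take on the order of ten
minutes of CPU; the seeds there are fixed arbitrary constants chosen
before the assertions were run.
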