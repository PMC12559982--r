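---
title: "Model, decomposition and estimators in calyxstp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, decomposition and estimators in calyxstp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calyxstp)
```

# Scope

`calyxstp` dissects synaptic strength and short-term plasticity (STP) at
large glutamatergic terminals such as the calyx of Held into two separable
ingredients: the *priming equilibrium* — how many docked synaptic vesicles
(SVs) sit in a fusion-competent, tightly docked state at rest — and the
*fusion probability* of such a vesicle per action potential (AP). The
package provides (i) a kinetic model of sequential SV priming and fusion
with a hybrid ODE/event simulator, (ii) a constrained non-negative tensor
factorization (NTF) that decomposes cohorts of quantal-content trains into
per-synapse component amplitudes and shared release time courses, (iii)
pool-size and fusion-probability estimators with the classical train
metrics, and (iv) a seeded synthetic cohort generator that makes the whole
pipeline testable end to end.

# The two-step priming and fusion scheme

A fixed number `N_total` of release sites cycles through five states:

* **ES** — empty sites available for docking;
* **LS** — loosely docked SVs (immature release machinery);
* **TS** — tightly docked, fusion-competent SVs;
* **TSL** — a short-lived, labile tightly docked state, populated from LS
  immediately after each AP (fraction `kappa_TSL`) and decaying back with
  rate `b3 = 1/tau_TSL`;
* **ERS** — empty refractory sites left behind by fusion, recovering to ES
  with rate `b4`.

Between stimuli the occupancies follow linear mass-action kinetics

```
dES/dt  = -k1*ES + b1*LS + b4*ERS
dLS/dt  =  k1*ES - (b1 + k2)*LS + b2*TS + b3*TSL
dTS/dt  =  k2*LS - b2*TS
dTSL/dt = -b3*TSL
dERS/dt = -b4*ERS
```

with site conservation `ES + LS + TS + TSL + ERS = N_total`. The two
forward rates are linear functions of the "effective" intracellular
calcium,

```
k1(t) = k1_rest + sigma1 * ([Ca](t) - ca_rest)
k2(t) = k2_rest + sigma2 * ([Ca](t) - ca_rest)
```

clamped at zero below rest (rates are physical quantities; the clamp only
matters for hypothetical sub-resting calcium). All backward rates are
fixed. Only TS and TSL vesicles fuse.

## The effective calcium transient

Each AP contributes a phenomenological calcium transient. Two
parameterisations are supported (`ca_transient_parameters()`): a single
bi-exponentially decaying global transient, and the sum of a large,
sub-millisecond *local* component (amplitude `amp_local`, decay
`tau_local`) and a small, slow *global* component (`amp_global`, fast/slow
decay pair). In the default local-plus-global parameterisation the local
component carries ~16% of the calcium time integral and the global
component the rest — the configuration that reconciles a shallow calcium
dependence of the priming equilibrium at rest with strong
activity-dependent acceleration during trains.

The transient of one AP is written relative to that stimulus only, which
leaves the treatment of overlapping transients open. The package defaults
to **additive** summation (linear superposition of all past APs'
transients, appropriate in a linear buffering regime) and offers a
**reset** mode (only the most recent AP contributes) as a switch, because
the two readings bracket the plausible behaviour and differ only at high
stimulation frequencies.

## Influx facilitation and depression, and the per-stimulus fusion probability

Presynaptic calcium influx itself facilitates and depresses during trains.
Two scalar factors track this: `y` (facilitation) is incremented towards a
ceiling at each AP, `y <- y + y_inc*(y_max - y)`, and `z` (depression) is
decremented towards a floor, `z <- z - z_dec*(z - z_min)`; between stimuli
both relax exponentially back to 1 (`tau_y`, `tau_z`). The product `y*z`
scales the amplitude of each AP's calcium transient.

The per-stimulus fusion probability is coupled to the same influx scale:

```
p_j = min(1, p_fusion * (y*z)^n),   n = p_cooperativity (default 4)
```

evaluated with the `y`, `z` values *immediately before* the stimulus, so
the first AP of a train from rest always uses `p_fusion` exactly. The
fourth-power default reflects the classical steep cooperativity of vesicle
fusion with respect to intracellular calcium at this synapse. The exponent
is a package design decision: with a constant within-train `p_fusion` the
scheme cannot produce net paired-pulse facilitation at 200 Hz with the
published control parameters (the labile-state transfer alone replaces at
most `kappa_TSL*LS` vesicles, which is smaller than the fused fraction of
TS), while the influx-coupled probability reproduces it. Setting
`p_cooperativity = 0` recovers the constant-probability reading.

## Events at a stimulus

At each stimulus time, in order:

1. release `m_j = p_j * (TS + TSL)` (quantal content, an expected value —
   the simulator is deterministic; stochasticity lives in the generator);
2. decrement TS and TSL by their fused fractions; increment ERS by `m_j`;
3. transfer `kappa_TSL * LS` from LS to TSL;
4. update `y`, `z` and add the AP's transient with amplitude scaled by the
   updated `y*z`.

Fusion uses the pre-AP state ("evaluated immediately before stimulus
arrival"); the labile transfer happens "immediately after" the AP. Whether
the transfer fraction applies before or after fusion is moot because
fusion does not consume LS.

# Numerics

Between stimuli the three coupled states (ES, LS, TS) are integrated with
`deSolve::lsoda` at relative tolerance `1e-10` (default; tests verify that
halving the tolerance changes every `m_j` by less than `1e-4` relative).
TSL and ERS decay independently and are propagated in closed form, as is
the calcium transient, which within a segment is a fixed sum of three
exponentials whose segment-start amplitudes accumulate across APs.
Integration restarts at every stimulus (the state and the transient are
discontinuous there); trajectories are sampled at 1 kHz by default, which
resolves the 5 ms inter-stimulus interval at 200 Hz. Site conservation
holds to better than `1e-10` relative along all tested protocols, and any
state excursion below `-1e-6 * N_total` aborts the run with the offending
time.

Degenerate parameters are treated as limits, not errors: `b1 = 0` or
`b2 = 0` drain the equilibrium into the downstream state;
`half_max_ca()` bisects the closed-form TS occupancy over
`[ca_ref, 10 uM]` to 0.01 nM and fails explicitly if the bracket does not
contain the half-maximum target.

One nuance worth knowing: "pure depression" (no calcium sensitivity, no
labile transfer, no influx dynamics) yields strictly decreasing `m_j` only
when fused sites leave the cycle (`b4 = 0`). With site recycling the
fusion→ERS→ES loop is irreversible, the relaxation spectrum is complex,
and the approach to steady state carries a weakly damped mode — a rebound
of order 0.1% of `m_1` around stimulus 30 at 10 Hz. The tests assert
strict monotonicity for the sink case and a `< 0.5%` rebound bound with
recycling.

# Equilibrium analysis

At constant calcium, TSL and ERS are empty and the remaining states obey
`LS/ES = k1/b1`, `TS/LS = k2/b2`, scaled to `N_total`
(`equilibrium_occupancy()`). Derived quantities: the fast-releasing pool
(FRP) fraction `(LS+TS)/N_total`; the calcium concentration at which the
TS occupancy reaches half of its maximal possible increase
(`half_max_ca()`; ~438 nM for the control parameter set — the priming
equilibrium is deliberately insensitive to small changes in resting
calcium); and the Michaelis–Menten influx ratio between two external
calcium concentrations (`influx_ratio_mm()`, EC50 2.6 mM).

# The NTF decomposition

## Model

For a cohort of `N` synapses stimulated with 40-stimulus trains at
5–200 Hz (plus 100/200 Hz trains preconditioned with two or four stimuli
at 10 Hz — ten layers in total), the quantal contents form a tensor
`X[stimulus, synapse, layer]`. The decomposition writes

```
X[j, s, l] ≈ sum_c  M_c[s] * BF_c[j, l]
```

with per-synapse amplitudes `M_c` shared across layers and base functions
`BF_c` shared across synapses within a layer, each normalised to unit
cumulative sum. Stage one uses two components (TS and LS∪RS) for 200
multiplicative least-squares iterations; stage two freezes the TS base
functions, splits the remainder into pre-existing loosely docked (LS) and
newly recruited (RS) vesicles, and runs 100 iterations. The first entry of
`BF_TS` is tied (projection by averaging) across the *unconditioned*
layers — preconditioned trains start from a partially depleted tight pool,
so their initial release fraction is legitimately lower and is left free —
and estimates the initial fusion probability; `M_TS` estimates the number
of tightly docked vesicles at rest.

## Identifiability and the anchor constraints

With free per-layer shapes the two-component model is invariant under
remixing: moving a multiple of one base function into the other while
adjusting the per-synapse amplitudes changes nothing that the summed
squared error can see. We verified this directly — fixing the TS base
functions at the exact (tagged-cohort) truth gives the same residual as a
badly drifted solution — so the split must come from constraints, not from
the fit. Two model-derived anchors close the gap, both enforced after
every update:

* vesicles that were not tightly docked at rest contribute nothing to the
  first response: every non-TS base function has a near-zero first entry;
* the cohort of initially tightly docked vesicles is consumed before the
  end of a high-frequency train (tagged-cohort simulation: > 99.5% by
  stimulus 25 at >= 100 Hz): the TS base function of >= 100 Hz layers has a
  near-zero tail from stimulus 26 on (`tail_start`, `tail_layers`
  arguments; results are insensitive to starting the pinned tail at
  stimulus 21, 26 or 31).

`BF_TS` is initialised as a geometric decay fitted to the cohort mean
trace; the stage-two LS and RS base functions start from archetypal
shapes — an early hump (one maturation step) and a late saturating ramp
(recruitment plus two maturation steps) — both silent at stimulus one.

## Known bias and the iteration budget

The shared-base-function model is mildly misspecified for a heterogeneous
cohort (each synapse's true TS time course depends on its own priming
equilibrium), and the slowly improving fit direction transfers a small
multiple of each synapse's LS content out of `M_TS`. At the fixed
200-iteration budget this leaves the `m1`-vs-`M_TS` regression slope with
a positive bias of roughly 10% (range +7% to +15% across generator seeds
at the default cohort design); the per-synapse *ranking* of `M_TS` is
essentially unaffected (Spearman correlation with truth > 0.99). The
iteration budget is therefore part of the estimator definition.
Validation tests assert recovery within ±15%.

## The LS/RS split

The three-component stage does not by itself separate pre-existing LS
vesicles from newly recruited ones; the mean `M_LS` is steered towards an
independent target, `FRP - mean(M_TS)` (`mls_target_value()`), by shifting
it 30% of the remaining distance per iteration (configurable within the
25–35% working range) via proportional rescaling of the `M_LS` column with
a compensating, non-negativity-respecting adjustment of `M_RS`.
Proportional (rather than additive) rescaling preserves the across-synapse
pattern, which is the information the target cannot supply.

# Pool and STP estimators

* `frp_apparent()` — cumulative release vs stimulus index; a straight line
  fitted to the last 10 of 40 points (the replenishment-dominated steady
  state; window exposed as an argument) is extrapolated to index 0. The
  intercept absorbs the depleted pool, the slope the replenishment rate.
* `frp_extrapolate()` — the apparent pools at 50/100/200 Hz underestimate
  the resting pool because depletion is incomplete; regressing `1/FRP'`
  on the inter-stimulus interval and taking the reciprocal intercept at
  ISI = 0 corrects this. The correction inherits a bias of its own: on
  simulated control trains `1/FRP'` is mildly convex in ISI, so the
  three-point line overestimates the pool by ~10–14%. This is a property
  of the published estimator, not of its implementation; the end-to-end
  validation asserts recovery within 15%, and the `M_LS` target
  consequently inherits the same error.
* `pfusion_regression()` — regression through the origin of the initial
  quantal content (averaged over the six unconditioned frequencies) on
  `M_TS`; the slope is the cohort's initial fusion probability.
* `stp_metrics()` — `m5/m1` (low-frequency depression), `mmax/m1` with
  `m_max` over stimuli 2..40 (high-frequency facilitation), the
  paired-pulse ratio `m2/m1` (so "PPR at 5 ms" is the 200 Hz train and
  "at 10 ms" the 100 Hz train), and the steady-state depression
  `m_ss/m1`, where `m_ss` is the mean of the last five responses for
  measured/noisy trains and the final response for deterministic
  simulations (both conventions available).
* `quantal_content()` (peaks / q* with q* = −6.6 pA under kynurenate),
  `dcm_to_sv()` (80 aF per vesicle), `compound_probabilities()`
  (`F = f_TS * p_fusion`, `p_r = F * occupancy`, with the resting
  occupancy defaulting to the model-derived 1 − ES fraction ≈ 0.75 in the
  wrapper).

# The synthetic cohort generator

`generate_population()` emulates the recorded control cohort: all synapses
share the control kinetic constants except for log-normal per-synapse
dispersion of `N_total` (CV 0.35) and of `k2_rest` (CV 0.4). These two
dispersions were chosen once to reproduce the published cohort anchors —
initial quantal contents averaging ~184 SVs with a several-fold range, and
a mature docked fraction `f_TS` spanning roughly 0.28–0.59 — while the
fusion probability is uniform across synapses, which is precisely the
structure that makes fusion-probability recovery by the decomposition a
meaningful test. Measurement noise is multiplicative log-normal per
response (CV 0.1 by default), optionally preceded by binomial sampling of
fusion counts, and three repetitions are averaged, mirroring the recording
protocol. All randomness flows from a single Mersenne–Twister seed
recorded in the output; identical seeds give bit-identical tensors.

What the generator does *not* emulate — and hence what passing tests do
not establish about real recordings: postsynaptic receptor saturation,
desensitisation and series-resistance artefacts (assumed removed upstream
by the kynurenate protocol and off-line corrections); slow run-down or
run-up across the session; across-synapse variation of `p_fusion`,
`b`-rates or transient shape; and any departure of real quantal noise from
the multiplicative/binomial model. Preconditioned protocols continue the
10 Hz rhythm into the main train (a 100 ms gap), a convention choice the
data format records explicitly.

# Problem sizes used in validation

The packaged tests exercise a 12-synapse cohort for unit-level
decomposition checks and the full 50-synapse, ten-layer design (the
study's cohort size) for end-to-end parameter recovery; the acceptance
script regenerates the 50-synapse design from the seed it is given. These
sizes are the package's validation choices and match the scale of
typical cohort recordings.

# Known limitations

* The decomposition's component split rests on the two anchor constraints;
  on data where early non-TS release is substantial (e.g. very fast
  recruitment) the first-entry anchor would bias `M_TS` upward.
* The `m1`-vs-`M_TS` slope carries the ~+10% finite-budget bias described
  above; comparisons *between conditions* (ratios of slopes) are more
  robust than absolute values.
* The FRP back-extrapolation inherits the convexity bias of the published
  two-step procedure (~+10–14% on simulated control data).
* The effective-calcium description is phenomenological by construction:
  no spatial diffusion or buffering, and the influx-probability coupling
  exponent is fixed, not fitted.
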