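---
title: "Lesioning and repairing a spiking sensorimotor network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesioning and repairing a spiking sensorimotor network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikerepair)
```

# Overview

`spikerepair` is a closed-loop testbed for inverse-model neurostimulation.
A recurrent spiking network of sensorimotor cortex drives a planar
two-joint virtual arm; reward-modulated STDP trains the network to reach a
target; simulated lesions (cell silencing or synapse removal) degrade the
reach; the surviving circuit is probed with microstimulation; a kernel
adaptive filter learns the inverse map from motor-population responses to
the stimulation that evoked them; and the inverse model synthesizes a
repair stimulation pattern whose effect is quantified with spike-train and
behavioral metrics.

This vignette documents the models, the tunable parameters with their
defaults and units, the numerical choices, and what the synthetic testbed
does and does not establish about real neural tissue.

# The spiking network

## Architecture

Seven subpopulations, 704 units in total at full scale: 192 proprioceptive
spike generators (P, four groups of 48, one group per muscle), and two
cortical layers — sensory (ES = 192 excitatory, IS = 44 fast-spiking
inhibitory, ILS = 20 low-threshold inhibitory) and motor (EM/IM/ILM with
the same sizes).  P encodes muscle lengths and projects to ES; ES projects
to EM; both layers have recurrent excitation and feedback inhibition, and
EM projects weakly back to ES.  Unit ids are contiguous per population
(ES, IS, ILS, EM, IM, ILM, then P).

## Neuron and synapse model

Cells are clock-driven (dt = 0.1 ms) leaky integrate-and-fire units with
conductance-based synapses:

$$\tau_m \dot V = (V_{rest} - V - h) + \tau_m \sum_r g_r\, s_r(V)\,(E_r - V)$$

with AMPA ($E = 0$ mV, $\tau = 5$ ms), NMDA ($E = 0$ mV, $\tau = 150$ ms,
sigmoidal voltage gate $s(V) = 1/(1+e^{-(V+25)/12})$ standing in for the
magnesium block) and GABA_A ($E = -80$ mV, $\tau = 10$ ms).  The relative
refractory period is a post-spike threshold jump (decaying with
$\tau_{th}$) plus a decaying hyperpolarizing current $h$.  Three cell
kinds (excitatory, fast-spiking, low-threshold) differ in $\tau_m$,
threshold and refractory strength; low-threshold cells fire most readily.
This preserves the qualitative features the closed loop depends on
(recurrent E/I balance, NMDA voltage sensitivity, relative
refractoriness) with a standard point-neuron formulation.

Background activity is an independent Poisson AMPA input per neuron
(default 130 Hz at weight 0.5, subthreshold), representing unmodeled
surrounding tissue.

## Connectivity

Per-pair connection probabilities, weights and delays are not published
for the original model; they are exposed as a rule table
(`network_config()$conn`) whose defaults were calibrated once so that the
unlesioned trained network reaches its targets and the probe stimulation
(250 Hz at 10x background weight) visibly drives its target cell.  Key
defaults: P→ES (p = 0.25, w = 4), ES→EM (p = 0.30, trainable, initialized
uniformly on [0, 1]), feedback inhibition at p = 0.3.  Weights are
dimensionless conductance scales (1 unit ≈ 0.8 mV EPSP at rest); delays
are uniform per rule within 1–5 ms.

## Determinism and random streams

Every stochastic element (construction, background, P drive, stimulators,
lesions, probes, training) draws from its own named stream derived from a
master seed (`derive_seed()`); the simulator uses internal PCG32 streams,
so results are bit-reproducible across machines, and attaching a
stimulator cannot perturb the background draws.  This yields the property
that a lesioned and a lesioned-plus-stimulation run are spike-identical
before stimulation onset.

## Lesions

Cell ablation silences `round(f * |ES|)` randomly chosen ES cells
(outgoing silencing: the cell never spikes; its incoming synapses remain
but are inert) — 19 cells at f = 0.10.  Synapse lesions remove
`round(f * N_syn)` connections uniformly from the whole network.
Rounding is to nearest; silencing-vs-removal for cells is a design choice
documented here because the original description ("silencing neurons")
does not distinguish them.

# The virtual arm

The arm is a planar two-link chain (upper arm 30 cm, forearm 33 cm, adult
male scale) moving in the horizontal plane (no gravity), actuated by four
lumped muscle groups: shoulder extensor/flexor, elbow extensor/flexor.
This deliberately replaces the original 18-muscle musculoskeletal model:
the network interface only ever consists of 4 muscle excitations in and 4
mean group lengths out, so a lumped plant preserves the closed-loop
structure and its slow dynamics while remaining fully transparent.

Each group has Hill-type first-order activation dynamics
($\tau_{act} = 30$ ms, $\tau_{deact} = 60$ ms) and contributes torque
`gain * activation * length` with flexor/extensor sign at its joint
(gains 20 N m at the shoulder, 15 N m at the elbow).  The linear
force–length factor is deliberate: it gives antagonist co-contraction a
stable interior equilibrium (equilibrium-point control), without which
any constant net torque drives the joints to their limits and no
posture can be held.  A flag (`fl_scaling = FALSE`) recovers the pure
activation-proportional variant.  Joint accelerations follow the
standard two-link rigid-body equations with viscous damping
(3.0 N m s/rad, added for well-posedness), integrated by semi-implicit
Euler at 0.5 ms and synchronized with the network every 1 ms.  Joint
limits clamp with velocity zeroing.  Normalized group lengths are
affine in the joint angle, antagonist pairs summing to 1.

The start posture (shoulder 20°, elbow 105° interior; joint ranges
[−30°, 70°] and [55°, 155°]) was chosen so that the start sits at
mid-range of both joints while the two 15 cm targets (left = −x,
bottom = −y from the start hand position) sit at well-separated
equilibrium postures on opposite sides of mid-range, reached by
distinct muscle pairs (left: shoulder flexor with elbow flexor;
bottom: shoulder extensor with elbow extensor — the pairing differs
from the original 18-muscle arm because the lumped geometry differs).
The reach durations are 600 ms (left) and 500 ms (bottom).

# The sensorimotor loop

Muscle lengths are population-coded: each P group's units tile [0, 1]
with boxcar tuning (exactly one active unit per group at any length,
default peak rate 250 Hz).  Motor output is decoded by summing each EM
subpopulation's spikes (48 cells per muscle group at full scale) over an
80 ms sliding window and threshold-normalizing to [0, 1]; the default
threshold corresponds to saturation at ≈35 Hz per cell.  A 50 ms window
is mentioned as an alternative reading of the source description and is
available via `motor_decoder_config(window = 50)`; 80 ms is the default
and the two are not reconciled here.

## Reward-modulated STDP

Training uses a minimal reward-modulated eligibility-trace scheme on
the trainable projections (ES→EM and recurrent excitatory connections):
pre-before-post coincidences within 20 ms accumulate eligibility
(pairing kernel $e^{-\Delta t/10\,\mathrm{ms}}$); every reward
interval (50 ms) the hand's distance change to the target is converted
to a sign reward, and eligibility traces (decay 80 ms) scaled by the
learning rate update the weights, clamped to [0, 4].  Three additions
proved necessary for stable credit assignment and are defaults:

* a **time-matched reward baseline** — the per-interval running mean
  reward across episodes is subtracted, which removes the reward's
  strong temporal profile (early intervals almost always improve, late
  ones plateau) that otherwise masks late-movement credit;
* **global homeostatic scaling** — after each episode all trainable
  weights are rescaled to a fixed global mean, so plasticity
  redistributes drive between motor groups instead of growing without
  bound (per-cell scaling was rejected: it pins every motor cell's
  input and erases exactly the group-level drive differences the
  decoder reads out);
* **policy-local exploration** — closed-loop episodes in which random
  muscle groups receive brief extra efference "bumps" per 50 ms
  segment, so that credit is evaluated around the policy's own
  trajectory.  Global open-loop babbling (random excitations driving
  the arm with an efference copy to the commanded EM groups) is
  retained as an alternative mode; on this plant its posture
  distribution is too broad for the secondary joint's credit to
  survive averaging.

The learning rate anneals with a configurable half-life.  The exact
training dynamics of the original work are out of scope; this scheme
exists to produce a trained baseline whose reach the lesions can
degrade.

# Kernel machinery

Spike trains are mapped to a reproducing kernel Hilbert space via
intensity functions: spike times are smoothed with a causal rectangular
kernel of width $T$ and height $1/T$ (units 1/ms, 1 ms grid; $T$
defaults to the forward-response window, far above the typical
inter-spike interval).  The Schoenberg kernel between two trains is

$$K(\lambda_i, \lambda_j) = \exp\!\big(-a_\lambda \int (\lambda_i -
\lambda_j)^2 dt\big)$$

(trapezoid quadrature on the shared grid), and the multi-unit kernel is
the unweighted sum over units, bounded by the unit count $N$.  The
default $a_\lambda = 0.05$ follows the source's cross-validated value;
because the kernel scale depends on the intensity units and smoothing
width, `train_inverse_model()` can re-select $a_\lambda$ by k-fold
cross-validation over a grid, and the campaign preset fixes the value
selected once this way (see below).

KLMS performs stochastic gradient descent on the instantaneous error in
the RKHS, stored in representer form (centers + per-output
coefficients).  The quantized variant (QKLMS) merges an input into its
nearest center when the kernel-induced distance
$d^2 = K(u,u) + K(v,v) - 2K(u,v)$ falls below the quantization size;
`eps = 0` recovers plain KLMS exactly.  For multi-unit spike inputs
$K(u,u) = N$ grows with the population, so the update uses a normalized
step $\eta/K(u,u)$ (NLMS); $\eta$ defaults to 0.5.  A center cap bounds
memory; at the cap updates always merge.

# The inverse controller

Each lesion scenario is probed: one trial per surviving ES cell with a
single-cell stimulus (250 Hz, 200 ms, onset 100 ms, AMPA weight 10x
background), plus randomized multi-cell probes (1–10 cells, onset
100 ms, duration uniform on [100, 500] ms truncated to the trial).  The
training pair at step $t \in [100, 300)$ maps the EM response window
$[t - h(t),\, t + D]$ (history $h(t) = \min(t, D)$; forward delay
embedding $D$ = reach duration − 300 ms, i.e. 300 ms left / 200 ms
bottom) to the commanded ES rate vector at $t$ — the commanded rates,
not the measured ES response, are the regression target, keeping targets
noise-free.  Windows are represented on a fixed relative grid of length
$2D$ and zero-padded where history is missing, which realizes the
growing history window exactly.

The kernel parameter deserves a note on units.  With intensities in
1/ms on a millisecond grid and smoothing width $T = D$, typical
squared-distance integrals between this network's response windows are
of order 0.1–1 per unit, so the literature value $a_\lambda = 0.05$
(kept as the package-wide default) leaves the kernel nearly constant.
`train_inverse_model()` therefore supports k-fold cross-validation over
an $a_\lambda$ grid; run once on probe data it selects $a_\lambda = 10$,
and the campaign presets fix that value rather than re-running the
selection per scenario.

To derive a repair, the embedding window slides over the pre-lesion EM
response; the model predicts the ES rate vector at each step; negative
rates are clipped (stimulation through AMPA drive cannot be negative)
and rates below a small threshold (default 25 Hz in the campaign) are
zeroed; the resulting rate matrix over [100, 300) ms is realized as
inhomogeneous Poisson generators at 1 ms resolution.

# Evaluation metrics

SPIKE-distance and SPIKE-synchronization follow the published
parameter-free definitions; the dissimilarity profile is integrated
exactly over its piecewise-linear segments, with auxiliary spikes at the
window boundaries for edge correction, and coincidence windows adapt to
the local inter-spike interval (a single-spike train uses the trial
length).  Metrics are computed per matched unit pair (original cell k
vs repaired cell k) and averaged — the only reading under which
identical conditions give distance 0 — with an all-pairs mode available
for exploration.  The shifted-PETH correlation averages Pearson
correlations of 20 ms population histograms across the 19 start offsets
(1 ms steps).  Behavioral metrics are the final hand-to-target distance
and the mean point-wise distance to the original trajectory after
linear resampling to a 1 ms grid (durations are never mixed across
targets; a mismatch restricts comparison to the shorter trial with a
warning).

# Campaign presets and problem sizes

The `"full"` preset uses the complete 704-unit network, all surviving
ES cells' probes, 200 multi-cell probes, 1 ms pair steps and a 1 ms
kernel grid.  The `"mini"` preset — used by the test suite and the
acceptance script — divides the populations by 4 (176 units, 48 ES/EM
in four groups of 12), keeps the full trial durations and protocol
constants, trains for 400 episodes per target, subsamples training
pairs at 8 ms on a 2 ms kernel grid, uses 12 multi-cell probes, caps
the inverse model at 140 centers, and runs 40 random perturbations in
the correlation study.  These sizes were chosen so a complete
train-lesion-probe-repair campaign runs in under ten minutes on one
CPU while preserving the architecture's 4-group structure; they are
scaled-down study conditions, so the campaign's aggregate numbers are
directional analogs of the full-scale ones, not reproductions.

# What the synthetic testbed shows — and does not

Everything here is simulation: the "lesion" is exact and known, probing
is unlimited and noiseless at the recording side, and the plant is
stationary between probing and repair.  Passing tests therefore
demonstrate the internal consistency of the method — that an inverse
model trained on probe data can synthesize stimulation in this circuit
— not that the procedure would survive the variability, partial
observability and co-adaptation of real tissue.  The cell model is a
point-neuron reduction; the arm is a lumped 4-actuator plant; the
training rule is a minimal stand-in for the original reinforcement
scheme.

Two known limitations of the miniature testbed deserve emphasis.
First, equilibrium-point control makes behavior depend mainly on the
*ratios* of motor-group drives, which are nearly invariant to random
removal of 5–10% of sensory cells or synapses: lesions measurably
perturb spiking patterns, but their behavioral effect at mini scale is
small and often statistically undetectable — unlike in the original
event-driven network, whose collective dynamics were fragile.  Second,
with the noise level of the Poisson drive, single-cell probe responses
barely exceed trial-to-trial variability, so the inverse model resolves
aggregate drive better than per-cell structure, and the derived repair
stimulation restores behavior more reliably than it restores the exact
spike patterns.  The strongest and most robust reproduction is the
perturbation-study correlation between SPIKE-distance and behavioral
error; conclusions about relative metric behavior are the transferable
content.
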