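# spikerepair

Can targeted microstimulation repair a lesioned neural circuit?
`spikerepair` is an R package that studies this question end to end in
simulation: a biomimetic spiking network of sensorimotor cortex (704
units in 7 subpopulations) drives a planar two-joint virtual arm in a
closed loop and is trained by reward-modulated STDP to reach a target.
The network is then lesioned — by silencing a fraction of the sensory
excitatory (ES) cells or by deleting a fraction of all synapses — which
degrades the reach.  The surviving cells are probed with known
stimulation patterns, and a **kernel adaptive inverse model** of the
motor layer is trained on the probe stimulus–response pairs: a quantized
kernel least-mean-squares (QKLMS) filter in a reproducing kernel Hilbert
space on spike trains,

- intensity estimation: λ̂(t) = Σₘ g(t − tₘ), rectangular g of width T,
- Schoenberg kernel: K(λᵢ, λⱼ) = exp(−a_λ ∫ (λᵢ − λⱼ)² dt),
- multi-unit kernel: the unweighted sum over units,
- representer form: f(u) = Σᵢ αᵢ K(uᵢ, u).

Feeding the *pre-lesion* motor response through the inverse model yields
a repair neurostimulation pattern (per-ES-cell firing rates over the
100–300 ms window), which is injected through AMPA synapses at 10× the
background weight.  Restoration is quantified with SPIKE-distance,
SPIKE-synchronization, shifted-PETH correlation, and two behavioral
metrics (final distance to target, mean point-wise distance to the
original trajectory).

The package is aimed at computational neuroscientists and neural
engineers prototyping inverse-model neurocontrol and spike-train kernel
methods on a fully observable, reproducible testbed.

## Worked example

A miniature end-to-end scenario (populations scaled by 4; a full-scale
campaign uses `experiment_config("full")`):

```r
library(spikerepair)

cfg     <- experiment_config("mini")
fixture <- make_fixture(cfg, seed = 1)      # build + train the baseline
scen    <- run_scenario(fixture, target = "left", type = "cell",
                        fraction = 0.10, seed = 1)
print(scen$report, digits = 3)
```

which prints (about 6 minutes, most of it the STDP training):

```
  target type fraction spike_dist_lesioned spike_dist_repaired
1   left cell      0.1               0.197               0.199
  spike_sync_lesioned spike_sync_repaired peth_r_lesioned peth_r_repaired
1               0.467               0.491           0.443           0.471
  final_dist_original final_dist_lesioned final_dist_repaired
1                5.72                5.46                5.68
  pointwise_lesioned pointwise_repaired
1              0.372              0.364
```

The row compares the lesioned and the repaired trial against the
pre-lesion reference: SPIKE-distance (0 = identical spiking),
SPIKE-synchronization and shifted-PETH correlation (higher = closer to
the original activity — here repair raises synchronization from 0.467
to 0.491 and the PETH correlation from 0.443 to 0.471), then the final
hand-to-target distance and the mean point-wise trajectory distance in
cm.  Single scenarios are noisy at the miniature scale — the campaign
aggregates (`run_experiment()` over all 8 scenarios) are the meaningful
output.  `write_report()` turns a campaign into a summary CSV plus
trajectory/metric/sweep figures, and `exec/spikerepair` wraps the same
pipeline as a command line tool
(`spikerepair all --preset mini --seed 1 --out out/`).

See the methods vignette (`vignettes/methods.Rmd`) for what each moving
part models, which sizes the presets use, and the known limitations of
the miniature testbed.

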