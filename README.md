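# vestsim

Simulation of galvanic (direct-current) vestibular stimulation in an
irregular vestibular afferent, from the hair-cell synapse to the spike
train.

Vestibular afferents fire spontaneously at high rates, driven by
stochastic EPSCs from hair cells; galvanic vestibular stimulation (GVS)
shifts that activity up (cathodic current) or down (anodic current) in
a graded, naturalistic way. `vestsim` implements a mechanistic model of
this interaction and the analysis suite needed to quantify it:

* **axon** — a single-compartment conductance model (Na, high- and
  low-voltage-gated K, leak; gating `m,h,n,p,w,z`) integrated with
  exponential Euler at 0.01 ms, with online spike detection,

  `C_m dV/dt = -(I_Na + I_KH + I_KL + I_leak) + (i_syn + i_GVS)/A`,

* **synapse** — renewal EPSC trains (exponential inter-arrival
  intervals, mean `mu(t)`) rendered as biexponential currents with
  lognormal amplitude scale `K`,
* **galvanic pathway** — electrode current mapped to injected axonal
  current through a per-variant coupling and the non-quantal (NQ)
  calyx gain: `i_GVS = -c * g_NQ * i_ext`,
* **hair-cell adaptation** — fast/slow high-pass pathway
  `fr_adapt = G_f HP_{tau_f}[x] + G_s HP_{tau_s}[x]` (tau = 0.15 s,
  2 s) that retargets vesicle release via
  `mu = mu0 * fr_o / (fr_o + fr_adapt)` every `t_dmu`,
* **spikestats** — rates, ISI/CV regularity, CV-vs-ISI envelope
  conformance, rate-vs-current slopes with bootstrap CIs,
  double-exponential adaptation fits, sinusoidal half-cycle gain and
  phase, cluster-based permutation comparison of rate traces,
* **experiments** — reproducible, seeded runners for amplitude sweeps,
  long-step adaptation protocols, sinusoidal frequency sweeps and the
  combined closed-loop model, plus synthetic fixtures with known
  ground truth.

Three model variants ship in `inst/extdata/variants.yaml`: the original
published parameterization (`original_hk`), a high-conductance in vivo
variant with the NQ gain (`invivo_high_conductance`), and a
low-conductance in vitro (explant) variant
(`invitro_low_conductance`). See the methods vignette
(`vignettes/vestsim-model.Rmd`) for the model, parameter provenance and
calibration.

## Worked example

```r
library(vestsim)

res <- run_amplitude_sweep("original_hk",
                           amplitudes_uA = seq(-60, 30, by = 15),
                           n_neurons = 5, duration_ms = 3000, seed = 1)
res$per_amplitude
#>   amplitude_uA mean_rate  sd_rate
#> 1          -60  67.99258 3.653351
#> 2          -45  67.94356 1.902907
#> 3          -30  64.45898 3.059543
#> 4          -15  62.59397 2.028430
#> 5            0  55.87585 2.521969
#> 6           15  47.25463 1.529539
#> 7           30  39.95042 2.910190
res$curve
#> <response_curve> slope -0.378 sps/uA, 95% CI [-0.407, -0.350] over [-45, 45] uA
```

Cathodic (negative) current raises the firing rate from the ~55
spikes/s resting value toward a peak just cathodic of −45 uA, beyond
which the cathodic block (sodium inactivation at sustained
depolarization) bends the response back down; anodic current
suppresses firing. The slope over the linear region (about −0.4 to
−0.5 spikes/s per uA at the full study scale) is the model's galvanic
sensitivity without the non-quantal gain.

The closed-loop combined model (hair-cell adaptation retargeting
vesicle release on top of the NQ-amplified axonal response):

```r
full <- run_full_invivo(amplitudes_uA = seq(-50, 50, by = 25),
                        n_neurons = 5, duration_ms = 5000, seed = 1)
full$curve$slope
#> [1] -1.883919
```

A thin command-line front end is provided in `exec/vestsim`:

```sh
exec/vestsim run --experiment sine_sweep --config cfg.yaml --seed 1 --out out/
exec/vestsim params --variant invivo_high_conductance --show
```

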