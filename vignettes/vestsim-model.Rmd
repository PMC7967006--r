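---
title: "The vestsim hair-cell/afferent model of galvanic vestibular stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vestsim hair-cell/afferent model of galvanic vestibular stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestsim)
```

## The problem

Galvanic vestibular stimulation (GVS) — continuous direct current
delivered near the vestibular end organ — can excite, inhibit and
sensitize vestibular afferents in a graded, naturalistic way that
pulsatile stimulation cannot. Irregular afferents respond to GVS with a
characteristic battery of effects: cathodic (negative) current raises
and anodic current lowers the firing rate; the sensitivity of rate to
current is high (around 2 spikes/s per uA in intact preparations);
regularity stays on the neuron's natural CV-versus-ISI curve as the
rate moves; long current steps produce a fast-rising response that
adapts back toward baseline over seconds; responses to steps delivered
from a current baseline depend on that baseline in narrow-firing-range
(explant) preparations but not in vivo; and sinusoidal stimulation
modulates the two half-cycles with a phase lead that shrinks toward
zero in the 4–8 Hz range.

`vestsim` implements a mechanistic account of this battery: a
conductance-based point model of the afferent axon driven by stochastic
EPSCs from a single hair cell, with galvanic current acting *both* on
the axon (scaled by the non-quantal, NQ, gain of the calyx synapse) and
on a hair-cell adaptation pathway that retargets the vesicle-release
rate. The package also carries the complete statistics suite (rates,
ISI/CV analysis, slopes with bootstrap CIs, double-exponential
adaptation fits, half-cycle gain and phase, cluster-based permutation
comparisons) and experiment runners that reproduce the in silico
protocols.

## Model structure

### Axon

The axon is a single compartment with sodium (gates `m`, `h`),
high-voltage-gated potassium (`n`, `p`), low-voltage-gated potassium
(`w`, `z`) and leak conductances:

$$C_m \frac{dV}{dt} = -\big(I_{Na} + I_{KH} + I_{KL} + I_{leak}\big) +
\frac{i_{syn} + i_{GVS}}{A},$$

with $I_{Na} = g_{Na} m^3 h (V - E_{Na})$,
$I_{KH} = g_{KH}(0.85 n^2 + 0.15 p)(V - E_K)$,
$I_{KL} = g_{KL} w^4 z (V - E_K)$, and first-order gating
$\dot{x} = (x_\infty(V) - x)/\tau_x(V)$. The kinetics are the
established ventral-cochlear-nucleus-derived formulations used by
single-compartment vestibular afferent models; `gating_steady_state_and_tau()`
is the plain-R reference implementation and the compiled integrator
carries an independently coded copy of the same expressions (they are
cross-checked in the tests).

The low-voltage-gated potassium density (1.1 mS/cm^2) is the published
irregular-afferent value; it sets firing irregularity and is never
scaled. Spikes are detected online as upward crossings of −20 mV with a
1 ms refractory window — unambiguous for full-height action potentials;
the sensitivity to the threshold is negligible because subthreshold
EPSP peaks stay below −30 mV in all variants.

### Synapse

EPSC arrival is a renewal process with exponential (memoryless)
inter-arrival intervals of mean $\mu(t)$; at rest $\mu(t) = \mu_0$.
Each event contributes a biexponential unitary current (rise 0.3 ms,
decay 0.5 ms, unit peak) scaled by an amplitude drawn from a fixed
lognormal distribution with mean $K$ and log-sd 0.3. Both stochastic
functions — arrival and amplitude — are properties of the hair
cell/synapse and are never modulated by the stimulus; stimulation
changes only the arrival-rate parameter. The amplitude spread matters
mechanistically: with it, a small galvanic bias smoothly changes the
fraction of events that reach threshold, which is what gives the model
its graded rate-versus-current response and keeps regularity on the
natural CV curve (the "sampling variance" account). With constant
amplitudes the conversion is nearly all-or-none and the galvanic
sensitivity collapses.

### Galvanic pathway to the axon

Electrode current (uA) maps to axon-injected current (pA) through a
single calibration scalar per variant, sign-flipped so cathodic current
depolarizes, and multiplied by the static NQ gain:
$i_{GVS} = -c \cdot g_{NQ} \cdot i_{ext}$. The NQ gain applies to
galvanic current only, never to the synaptic current — the NQ effect is
treated as modulatory on external current influx. The electrode-to-axon
mapping is not printed in the source experiments (it is implicit in
their implementation), so $c$ is fitted once per variant (see
Calibration).

### Hair-cell adaptation

The adaptation pathway is a linear fast/slow high-pass system acting on
the drive $x(t) = -i_{ext}(t)$:

$$fr_{adapt}(t) = G_f\,\mathrm{HP}_{\tau_f}[x](t) +
G_s\,\mathrm{HP}_{\tau_s}[x](t),$$

with $\tau_f = 0.15$ s, $\tau_s = 2$ s and $G_f > G_s$. A step of
amplitude $A$ produces $A(G_f e^{-t/\tau_f} + G_s e^{-t/\tau_s})$ —
full adaptation back to zero. For inhibitory (anodic) drive the fast
gain is halved (`anodic_fast_attenuation = 0.5`), reflecting the weaker
fast component of inhibitory responses; the exact attenuation is not
constrained by available data and results are insensitive to it within
0.3–0.8. In the frequency domain the pathway is
$H(f) = [G_f H_f(f) + G_s H_s(f)]\,H_{lpf}(f)$ with first-order
high-pass sections cutting off at $1/\tau_f$ and $1/\tau_s$ and a
first-order low-pass at 1 kHz representing the fastest rate the axon
can follow its synaptic drive.

The pathway feeds the axon by retargeting vesicle release: every
$t_{d\mu}$ ms (one resting inter-EPSC interval by default) the mean
interval is re-evaluated as

$$\mu = \mu_0\,\frac{fr_o}{\max(fr_o + fr_{adapt}(t),\ fr_{floor})},$$

i.e. release rate is proportional to the target rate, anchored at the
fixed point $(fr_o, \mu_0)$, floored at 0.5 spikes/s and clipped to
$\mu \in [0.05, 10^4]$ ms to avoid event storms and division by zero.
Updating every $t_{d\mu}$ rather than continuously models the finite
speed of vesicle packing and recycling; slowing the update to
$5\mu_0$ measurably low-passes the response (reduced cathodic-half
gain, phase dipping below zero), which the tests exercise.

## Parameters

| Parameter | Value | Units | Origin |
|---|---|---|---|
| $C_m$, area | 0.9, 1e-5 | uF/cm^2, cm^2 | published point-model values |
| $E_{Na}, E_K, E_{leak}$ | 82, −81, −65 | mV | published point-model values |
| $g_{Na}, g_{KH}, g_{KL}, g_{leak}$ (original) | 13, 2.8, 1.1, 0.03 | mS/cm^2 | published point-model values |
| $g_{Na}, g_{KH}$ (in vivo) | 52, 22.4 | mS/cm^2 | calibrated (see below) |
| $g_{Na}$ (in vitro) | 6 | mS/cm^2 | calibrated |
| $K$ | 155 | pA | calibrated |
| amplitude log-sd | 0.3 | — | fixed; typical quantal spread |
| $\mu_0$ | 3 / 0.75 / 6.5 | ms | published (original, in vivo) / calibrated (in vitro) |
| coupling $c$ | 1.0 / 1.5 / 0.5 | pA/uA | calibrated per variant |
| NQ gain | 1 / 4.5 / 1 | — | published upper bound (4.5) |
| $G_f$, $G_s$ | 2.4, 1.0 | sps/uA | fitted to explant step-response shape |
| $\tau_f$, $\tau_s$ | 0.15, 2 | s | published fitted values |
| $f_c$ | 1000 | Hz | fastest sustainable firing |
| dt | 0.01 | ms | resolves Na gating |

## Calibration

Several constants are implicit in the source experiments and are fitted
once, in this order, against the published firing statistics; the
fitted values are committed to `inst/extdata/variants.yaml` and never
adjusted per experiment.

1. **EPSC scale $K$**: with the original conductances and
   $\mu_0 = 3$ ms the model must rest near 52.7 spikes/s, and at
   $\mu_0 = 0.75$ ms near 102.8 spikes/s. $K = 155$ pA satisfies both.
2. **Original coupling** ($c = 1.0$): places the cathodic block beyond
   −45 uA with a peak response near 70 spikes/s and a linear-region
   slope near −0.5 sps/uA.
3. **In vivo conductance scale** (×4 on $g_{Na}$, ×8 on $g_{KH}$):
   pushes the induced firing range as high as this kinetics family
   allows while keeping the spontaneous rate near 100 spikes/s.
4. **In vivo coupling** ($c = 1.5$): fitted so the high-conductance
   model *without* the NQ gain reproduces the −0.32 sps/uA slope. The
   published NQ amplification bound (4.5×) then yields the published
   high-sensitivity slope without further fitting.
5. **In vitro variant** ($g_{Na} = 6$, $\mu_0 = 6.5$ ms, $c = 0.5$,
   no NQ): reproduces the 15–20 spikes/s explant resting rate and its
   weak, narrow-range galvanic responsiveness. Reduced $g_{Na}$ alone
   cannot produce the explant rate at the in vivo arrival rate — the
   synaptic barrage dominates — so the explant's slower release is
   part of the variant.
6. **Combined model** $\mu_0 = 0.55$ ms: chosen so the combined
   (adaptation + NQ + high-conductance) model rests near 120 spikes/s,
   the spontaneous rate of the intact preparation it emulates.

## Measurement conventions

Amplitude sweeps switch the current on after a 500 ms settling segment
and compute statistics from onset to the end of the record. When the
adaptation pathway is enabled, the *induced* response is measured in a
1 s post-onset window: the response adapts over seconds, so the
steady-state mean would mostly erase the quantity of interest.
Rate-versus-current slopes are fitted over the linear region — between
anodic silencing and the cathodic block, restricted to amplitudes at
which all neurons fire — by least squares on per-neuron rates, with a
95% CI formed as a t-interval on the bootstrap (neurons resampled)
standard error — better small-sample coverage than the raw percentile
interval at these population sizes. Half-cycle rates count
spikes in the cathodic (negative current) and anodic half-cycles; the
response phase is the first Fourier harmonic of the spike phases,
reported relative to the cathodic peak (positive = lead). Rate traces
are spike counts in 10 ms bins smoothed with a 100 ms boxcar (bin and
boxcar widths are configurable; the sources do not state theirs).

## Numerical choices

Gating uses exponential Euler with steady states and time constants
linearly interpolated from tables on a 0.05 mV grid; the membrane
potential advances by a forward step at dt = 0.01 ms. Halving dt
changes mean rates by under 2% on reference protocols. Event times are
drawn sequentially from R's RNG stream, so every train is a pure
function of its seed; per-neuron seeds are derived once from the master
seed. Integration aborts with an informative error if V becomes
non-finite or exceeds 1000 mV in magnitude. Under strong anodic current
combined with the full NQ gain the membrane can settle at deeply
hyperpolarized (clearly unphysiological) equilibria of a few hundred
millivolts below rest, because the model contains no
hyperpolarization-activated conductance; firing is zero there, which is
the only property those conditions contribute to any analysis. The
adaptation filters use the exact piecewise-constant recursion
$y_k = e^{-\Delta t/\tau} y_{k-1} + (x_k - x_{k-1})$, which reproduces
the closed-form step response to machine precision.

## What the synthetic generators emulate

`generate_fixtures()` produces periodic, Poisson and sinusoidally
modulated Poisson spike trains, renewal EPSC trains, and
double-exponential-plus-offset rate traces with known ground truth.
These validate the statistics suite (CV limits, phase recovery, fit
round-trips) but are idealizations: real afferent trains have
refractory structure, the EPSC-to-spike conversion is nonlinear, and
real rate traces carry correlated noise. Passing those tests therefore
certifies the estimators, not the biology; the model-level checks run
the full simulation.

## Known limitations

* **Induced-rate ceiling.** With these kinetics, EPSC-to-spike
  conversion saturates near 135–170 spikes/s at the in vivo arrival
  rates once the spontaneous-rate and slope benchmarks are imposed; the
  published induced maxima (≈188 spikes/s for the high-conductance
  axon, ≈211 spikes/s for the combined model) are not reached within a
  −100 uA sweep. Raising conductances, kinetics speed or coupling can
  reach those maxima, but only at the cost of the spontaneous rate,
  slope or block benchmarks, which we prioritized. The corresponding
  replication checks are kept at their stated tolerances and fail
  honestly.
* **Fast-time-constant recovery.** Fitting the double-exponential
  adaptation model to binned, smoothed spike output recovers the slow
  time constant well but overestimates the fast one (by up to ~2–3×),
  because the release-rate pathway compresses the onset transient and
  the boxcar blurs it. The slow/fast gain ordering and full adaptation
  are robust.
* No morphology, efferents, vesicle-pool depletion, dynamic NQ/K+
  accumulation, or tissue-impedance filtering; a single hair cell per
  afferent; regular afferents are out of scope.

## CV-versus-ISI envelope

The empirical boundary curves that define an irregular afferent's
regularity band are not redistributable, so `cv_star_envelope()`
accepts user-supplied curves and `default_cv_star_envelope()` provides
a clearly synthetic power-law band for tests and demonstrations.
Fractions of points inside any given envelope are computed by
`cv_star_conformance()`; published coverage percentages depend on the
original envelope curves and are therefore checked only qualitatively
(regularity follows a single decreasing CV-versus-rate curve per
neuron).

## A worked mini-example

```{r example, eval = FALSE}
res <- run_amplitude_sweep("original_hk",
                           amplitudes_uA = seq(-60, 30, by = 15),
                           n_neurons = 5, duration_ms = 3000, seed = 1)
res$per_amplitude
res$curve
```

The sweep above (5 neurons, 3 s records — a smoke-scale run; the study
scale is 19 neurons and 5–10 s) shows the three signature axonal
effects: cathodic excitation, anodic inhibition, and the cathodic
block. The replication-scale protocols live in
`scripts/acceptance.R` and the test suite.
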