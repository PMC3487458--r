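---
title: "Modelling amplitude-modulation coding in the inferior colliculus with icsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amplitude-modulation coding in the inferior colliculus with icsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icsim)
```

## The scientific problem

Neurons of the inferior colliculus (IC) encode the envelope of sinusoidally
amplitude-modulated (AM) sounds both in their firing rate and in the timing
of their spikes relative to the modulation cycle.  A single IC neuron
receives a handful of ascending excitatory inputs (cochlear nuclei, superior
olive) and inhibitory inputs (nuclei of the lateral lemniscus), each with
its own rate and temporal modulation transfer function (MTF).  `icsim`
simulates how those converging inputs, the neuron's intrinsic conductances,
and short-term synaptic depression combine to produce the rate-MTF shapes
observed in vivo — low-pass (LP), band-pass (BP), all-pass (AP), band-reject
(BR) and high-pass (HP) — and how those shapes transform when GABAergic
inhibition is reduced, as happens in the aged auditory midbrain.

## The neuron model

The membrane is a single compartment,

$$C \frac{dV}{dt} = -\sum_i I_i - I_{leak} - I_{syn} + I_{inj},$$

with Hodgkin–Huxley-style currents $I_i = \bar g_i \prod_k x_k^{p_k}
f_{Ca}([Ca]) (V - E_i)$.  Gates follow first-order kinetics with Boltzmann
steady states and voltage-dependent time constants; integration is
exponential-Euler at a fixed step of 0.02 ms (steps above 0.05 ms are
rejected; spike counts for the pulse protocols are identical at 0.02 and
0.01 ms).  Calcium enters through T- and L-type channels into a single pool
that decays exponentially toward a floor; SK channels are gated by a Hill
function of pool calcium (coefficient 4) and BK channels by a voltage gate
whose half-activation shifts with calcium.

Six presets reproduce the firing classes reported in IC slice work:

```{r presets}
vapply(c("sustained", "adapting", "pause_build", "rebound_sustained",
         "rebound_transient", "onset"),
       function(p) paste(vapply(make_preset(p)$channels, `[[`, "", "name"),
                         collapse = " "), "")
```

The kinetic constants are reconstructed from the rodent auditory literature
(the Rothman–Manis family for Na, delayed-rectifier and low-threshold K;
standard Ih, T/L-type Ca, SK and BK forms) and then calibrated, because no
single published set reproduces all six firing classes on one passive
backbone.  Every constant is tagged `"cited"` or `"calibrated"` in the
channel library.  The calibration targets are the printed passive
properties: the Sustained preset rests at −70 mV with an input resistance of
146 MΩ and a membrane time constant of 4.4 ms; the Adapting preset at
−70 mV with 142 MΩ and 5 ms.  Capacitance was fixed first (30.15 pF for the
Sustained family; 38.8 pF for the Adapting family, since 142 MΩ × 30 pF
would give a time constant outside the printed value), then the leak
conductance was tuned to the input resistance and the leak reversal to the
resting potential, with the standing Ih and T-window currents included in
the balance.  Two kinetic choices matter for robustness: sodium
inactivation half-voltage sits at −55 mV so that firing persists at strong
depolarizations instead of damping into depolarization block, and the
onset preset's low-threshold potassium conductance deactivates slowly
(tens of ms), which is what limits it to a single spike per pulse.

```{r passive}
unlist(measure_passive(make_preset("sustained")))
unlist(measure_passive(make_preset("adapting")))
```

A bias current, found by root-finding on the settled membrane potential, is
applied throughout each simulation (at least 200 ms before stimulation) to
hold the cell between −64 and −56 mV, the range seen in vivo.

## Synapses and short-term depression

Excitatory events drive AMPA (τ 0.5/3 ms) and NMDA (τ 5/80 ms, standard
magnesium block) conductances; inhibitory events drive GABA_A (τ 1/10 ms,
E = −75 mV).  Kernels are dual exponentials normalized to peak at `g_peak`.
AMPA and GABA_A amplitudes depress: each afferent carries an availability
that is multiplied by `d` (AMPA 0.55, GABA_A 0.6) at every event and
recovers exponentially (AMPA 40 ms, GABA_A 50 ms).  This is the minimal
interval-dependent amplitude-scale model with one amplitude knob and one
recovery time constant — exactly the two quantities the model experiments
manipulate.  NMDA is undepressed.  Depression operates per afferent: each
input train has its own availability.  The depression constants are free
calibration parameters fit only to the qualitative paired-pulse ordering
(10 ms ISI response < 25 ms ISI response < unconditioned response).

## MTF-shaped input generation

Each afferent class is a pair of curves over the stimulus grid
(8–1024 Hz in octave steps): firing rate and target vector strength (VS).
Trains are generated per modulation cycle: a Poisson count with mean
`rate / mod_freq`, each spike's phase drawn from a von Mises distribution
whose concentration solves $I_1(\kappa)/I_0(\kappa) = VS$.  This
construction controls rate and synchrony independently, which is exactly
how the afferent classes are specified; any generator matching both curves
would be admissible.  Sampling uses the Best–Fisher rejection method, and
the concentration root is checked against a 10⁶-sample Monte-Carlo oracle
in the tests.

Preset classes: LSO (low-pass rate, corner 64 Hz; synchrony rising to a
maximum near 64 Hz then cutting off — low-frequency envelopes are tracked
less precisely than mid frequencies), DCN (shallow monotone-increasing
rate, low-pass synchrony), VCN (flat rate, band-pass synchrony at 128 Hz),
DNLL (all-pass or high-pass rate, low-pass synchrony), VNLL (band-pass or
high-pass rate, band-pass synchrony between 64 and 128 Hz).  Peak rates for
the lemniscal classes are not published and are exposed as scale
parameters.  The VNLL band-pass class carries a configurable low-frequency
shoulder (default 40 spikes/s, rolling off above ~90 Hz), reflecting the
residual low-modulation-frequency response of VNLL units; it is the
parameter that lets tuned inhibition keep suppressing low modulation
frequencies after a conductance reduction.

Seeds: every (master seed, trial, afferent) triple maps to its own stream;
inhibitory afferents use an offset index block, so excitatory and
inhibitory trains are statistically independent and every comparison can
reuse identical trains.

## Analysis

Vector strength is the resultant length of spike phases,
$VS = \frac{1}{n}\sqrt{(\sum\cos\phi_i)^2 + (\sum\sin\phi_i)^2}$, computed
on spikes pooled across trials in the 50–750 ms window; significance is the
Rayleigh statistic $2nVS^2 > 13.8$ (p < 0.001).  Rates use the full
stimulus duration.  Rate-MTF shapes are classified from the normalized
curve with thresholds 0.75 and 2/3, evaluated in the order BR, BP, LP, HP,
AP: BR needs a contiguous sub-2/3 run strictly inside the range with
recovery to ≥ 0.75 on both flanks.  The printed criterion wavers between
66% and 67%; the implementation uses exactly 2/3, and the boundary is
unit-tested on both sides.  tBMF is the significantly synchronized
frequency with the greatest VS (ties to the lower frequency), Fmax the
highest significant frequency.  Pooling across trials (rather than
averaging per-trial VS) matches how 10-trial rasters are analysed; a
response is labelled "onset" when ≥ 80% of spikes fall in the first 50 ms
(the designation is used without a printed criterion; the 80% cut is this
package's choice).

## Worked scenarios

`ic_recipe()` ships the input-convergence configurations used in the model
experiments, each with calibrated conductances.  The acceptance property of
a recipe is its qualitative shape or shape transformation, not its absolute
rates:

```{r recipe, eval = FALSE}
m <- run_am_experiment(ic_recipe("lp_vcn_dnll", n_trials = 10, seed = 1))
m$rate_shape   # "LP"
m$sync_shape   # "LP"
```

Calibration notes, where the design was genuinely open:

* `bp_lp_inhibition`: band-pass tuning from purely low-pass inputs arises
  here when the inhibitory corner (8 Hz) sits below the excitatory corner
  (32 Hz), the "equal or higher excitatory corner" arrangement.  With both
  corners at 32 Hz the output stays low-pass in this implementation, so the
  shipped recipe uses the staggered corners.
* `aging_lp` (low-pass unit, Sustained, 2 LSO + 3 DNLL all-pass at −58 mV):
  calibrated NMDA-dominant (AMPA 0.5 nS, NMDA 2.6 nS with 150 ms decay,
  GABA_A 12 nS).  The slow NMDA component smooths the excitatory drive, so
  the young neuron's synchrony comes from phase-locked inhibition gating
  tonic excitation; halving GABA_A then raises rates at every modulation
  frequency and pushes every Rayleigh value below 13.8.  With an
  AMPA-dominant drive the inherited 8 Hz phase locking survives any
  inhibition reduction at these spike counts.
* `aging_br` (3 VCN + 4 VNLL band-pass at 32 Hz): with the VNLL low
  shoulder, inhibition suppresses 8–64 Hz while ≥ 256 Hz is inhibition-free;
  at a 75% conductance reduction the residual low-side suppression leaves a
  high-pass rate MTF.  In this implementation the intact-inhibition
  response is already high-pass rather than band-reject — suppression of
  the low flank and of the dip region scale together, so a band-reject
  young shape and a high-pass aged shape are mutually exclusive under pure
  conductance scaling; the band-reject young phenotype is carried by the
  separate `br_vnll` recipe (weak shoulder), and the high-pass aged
  transformation by this one.
* Membrane-potential contours: the comparison of 2–3 versus 7–9 excitatory
  inputs holds the total excitatory conductance fixed (per-afferent peak
  scaled by 3/n), isolating the temporal interleaving effect — fewer,
  larger inputs give more phasic, peaked contours; more, smaller inputs
  track the AM envelope smoothly.

## Problem sizes and determinism

The shipped protocol is 10 trials × 8 modulation frequencies × 750 ms at
dt = 0.02 ms.  The test suite runs reduced versions chosen for routine
execution: the 5×5 conductance × IPSC-decay sweep uses 2 trials per cell,
the plasticity ablations 4 trials, and the aging comparisons the full 10
trials; the miniature `toy_scenario()` (2+2 afferents, 3 frequencies,
200 ms, 2 trials) exercises the full path in seconds.  All stochasticity
lives in the input generator; the integrator is deterministic, so paired
comparisons attribute every difference to the manipulated parameter.

## What the generator does and does not emulate

The synthetic afferents reproduce stationary rate and synchrony per
modulation frequency with Poisson cycle counts.  They have no onset
adaptation, no refractoriness, no across-cycle rate correlations, no
level dependence and no tonotopy; excitatory and inhibitory trains are
exactly independent, whereas in vivo they may be correlated (which would
make conduction delays matter more than they do here).  Passing tests
therefore show that the cellular/synaptic machinery transforms idealized
MTF-shaped inputs as described, not that real IC afferents are fully
captured.

## Known limitations

Point neuron (no dendritic filtering); aggregate synaptic classes rather
than source-specific kinetics; channel kinetics calibrated rather than
transcribed; the band-reject-to-high-pass aging transformation holds as a
0.25-scale endpoint property, not as the full BR → shallow BR → HP
sequence; temperature (Q10) handling is omitted, with all kinetics defined
at simulation temperature.
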