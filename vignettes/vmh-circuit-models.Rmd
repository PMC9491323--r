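---
title: "Circuit models of the VMH assessment-flight switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit models of the VMH assessment-flight switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmhswitch)
```

## The scientific question

Mice approaching a threat show a sudden, reciprocal change in the firing of
two populations of ventromedial hypothalamus (VMH) neurons: Assessment+
cells, whose firing grows as the animal closes in on the threat, abruptly
shut down at the moment of flight, while Flight+ cells abruptly switch on.
The switch appears to be *thresholded to the intensity of sensory input*:
the stronger the stimulus ramps up, the earlier it occurs. This package
implements a family of spiking circuit models asking which local circuit
features — input asymmetry, feedback-inhibition asymmetry, short-term
synaptic plasticity, slow rebound excitation, exclusive versus random
feedback wiring — are sufficient for such a sensory-thresholded switch to
emerge.

## Circuit architecture

All variants share a three-stage architecture:

* **Amygdala** (100 excitatory neurons, not interconnected) receives the
  sensory drive as an inhomogeneous Poisson spike stream, one independent
  stream per neuron, and projects onto both core populations. The
  amygdala-to-Flight connection density is the amygdala-to-Assessment
  density multiplied by `r_input` (0–1).
* **VMH core**: two interconnected excitatory populations of 100 neurons,
  *Assessment* and *Flight*.
* **VMH shell**: inhibitory feedback neurons. In models 1–3 the wiring is
  *exclusive*: 20 ShellA neurons driven by Assessment inhibit only Flight,
  and 20 ShellF neurons driven by Flight inhibit only Assessment. Model 4
  merges them into one randomly wired population of 40.

Neurons are leaky integrate-and-fire units with exponentially decaying
postsynaptic currents and Bernoulli (probabilistic-release) synapses.
Membrane constants follow slice electrophysiology of VMH neurons: core
cells rest at −58.6 mV, spike at −43.1 mV, and integrate with a 40.3 ms
time constant; shell cells rest at −56.5 mV, spike at −42 mV, with
τ = 41.6 ms and a higher background noise rate (10 Hz vs 5 Hz). Capacitance
(200 pF), reset-to-rest, and a 2 ms refractory period are standard
cortical-scale choices, exposed in the configuration.

The five variants:

| variant | mechanism |
|---|---|
| `model1` | asymmetric input density (`r_input`) + asymmetric feedback (`r_feedback` scales shell→Assessment weights) |
| `model2` | Tsodyks–Markram short-term plasticity on all core outputs, symmetric feedback |
| `hybrid` | model 1's asymmetric feedback plus model 2's plasticity |
| `model3` | slow excitatory rebound paired with inhibitory inputs onto Flight cells |
| `model4` | rebound as model 3, with the single randomly wired shell |

## Sensory input

Each 20 s trial has a 10 s approach phase in which the amygdala drive rises
linearly with slope `a = f_max/10` Hz/s from the 40 Hz baseline, and a 10 s
flight phase in which it falls four times faster (a mouse flees faster than
it approaches), clipped below at baseline. A session is ten consecutive
trials with 6 s inter-trial intervals and 2 s buffers (258 s). Spike
streams are generated by thinning against the peak rate.

## Plasticity and rebound

Short-term plasticity follows the Tsodyks–Markram utilization/resource
scheme with the update order decay → facilitate → release → deplete, stated
explicitly because orderings differ between simulators. The delivered
amplitude is normalized by the baseline utilization `U` so the first spike
from rest transmits the nominal weight, keeping plastic and static circuits
comparable at stimulus onset. Defaults (`U = 0.5`,
`tau_facilitation = 3158 ms`, `tau_depression = 527 ms`) are the
representative plasticity configuration.

Rebound excitation is implemented as a deterministic relay: every
presynaptic spike on a rebound-equipped inhibitory edge (shell→Flight in
models 3 and 4) schedules, `t_delay` after the inhibitory arrival, one
excitatory kernel of amplitude `w_rebound` decaying with `tau_rebound`.
Release on this pathway is non-probabilistic, independent of the fast
inhibitory Bernoulli draw — the relay stands in for an intermediate
population with reliable synapses, and reproduces its transfer function
without extra spiking units. The delay (14 ms) and time constant (10 ms)
are the experimentally estimated values. Whether the original intermediate
units should themselves be spiking integrators (which would low-pass filter
shell activity) is left as an extension.

## The simulation engine

The engine is a clock-driven integrator (0.1 ms steps) written in C++.
Per step it decays the three per-neuron current accumulators (fast
excitatory τ = 2 ms, fast inhibitory τ = 5 ms, slow rebound), delivers due
events, advances every membrane with the exact exponential update for a
current held constant over the step, applies threshold/reset/refractory
rules, and schedules downstream deliveries at spike time plus the
per-edge delay. Two numerical choices matter:

* The membrane update uses the *step-mean* of the exponentially decaying
  current rather than its start-of-step value. The start-of-step choice
  over-integrates each synaptic event's charge by a factor
  `(dt/τ_syn)/(1−exp(−dt/τ_syn))` (≈ 2.5% at dt = 0.1 ms, τ = 2 ms), which
  is visible as a systematic rate change when dt is halved; the step-mean
  removes the bias, and halving dt then changes population rates by well
  under 2% in feedforward configurations. In the recurrent network a
  deterministic dt limit does not exist — timing quantization is amplified
  chaotically — so convergence is assessed feedforward.
* All randomness derives from one seed, split into sub-seeds for input,
  noise and release, so a prebuilt network's connectivity is unaffected by
  the run seed and identical seeds give bit-identical spike records. Event
  ties within a step are processed in (presynaptic, postsynaptic) order.

## Calibration of unprinted constants

The published description fixes the membrane constants, population sizes,
the stimulus schedule, the plasticity and rebound time-constant ranges, and
the representative parameter points — but not the connection probabilities,
synaptic weights, input/noise weights, or per-model peak input rates. Those
were calibrated once, with the procedure shipped in
`inst/scripts/calibrate.R`, and frozen as `circuit_defaults()`:

* `w_noise` (800 pA) makes an unconnected core neuron fire ~0.5–2 Hz from
  its 5 Hz background source alone.
* `w_input` (600 pA) keeps amygdala neurons active at the 40 Hz baseline
  and tracking the ramp smoothly to ~50 Hz; a baseline-silent amygdala
  ignites abruptly mid-ramp, which destroys the gradual Assessment onset.
* Densities were raised (core→core 0.3, core→shell 0.8, shell→core 1.0,
  amygdala→core 0.4) with correspondingly smaller weights: at sparser
  wiring the per-neuron binomial spread in the number of inhibitory inputs
  dominates the dynamics and the trial outcome flips between network
  realizations.
* The core/shell weights place the shell deep in its saturating
  (logarithmic) response range during the ramp, so Flight's rising direct
  and recurrent drive eventually outgrows its saturating inhibition and
  breaks through late in the approach phase, while the
  Flight→ShellF→Assessment loop gain stays high enough to collapse
  Assessment at the flip.
* In the rebound variants the rebound charge per inhibitory spike
  (`w_rebound · tau_rebound`) is kept below the fast inhibitory charge, so
  Flight remains suppressed during Assessment's ignition and escapes only
  once shell firing is strong and patterned; the variant-specific feedback
  weights compensate for the charge the rebound hands back.
* Plastic (model 2 / hybrid) core outputs transmit only ~1/8 of their
  nominal amplitude at ramp firing rates (depression-dominated steady
  state), so their nominal weights are several-fold larger.

A consequence worth stating plainly: with these calibrated defaults the
representative model 1 and model 3 configurations classify as Switch
(model 1 in 10/10 trials of the default session), model 2 produces
intermittent reciprocal firing but no stable switch anywhere on its small
default grid, and model 4 shows reliable, sensory-thresholded switch
*onsets* but its trials mostly classify Intermittent rather than passing
all five Switch criteria — the published model 4 achieved stable switching
with parameter values we do not have. Latency analyses use per-model peak
rate ranges (model 1: 170–260 Hz, model 3: 160–250 Hz, model 4: 130–190 Hz)
because each calibrated variant thresholds in a different input range, as
the original per-model `f_max` values did.

## Switch detection and classification

Population PSTHs are raw 20 ms bins (no smoothing — smoothing would blur
the "sudden" criteria). The switch onset in a trial is the first bin where
the Flight rate exceeds the Assessment rate by more than 25% of the larger
of the two PSTH maxima over that trial (per-trial maxima; the whole-session
alternative changes little but per-trial is scale-covariant trial by
trial).

A trial is a **Switch** when all five criteria hold:

1. Assessment onset gradual (10–90% rise ≥ 2 s), decrease sudden
   (90–10% fall ≤ 0.5 s across the switch);
2. Flight onset sudden (≤ 0.5 s), decrease gradual (≥ 0.6 s — smaller than
   the 2 s rise bound because the flight-phase input falls four times
   faster than the approach rises, so even an input-tracking decay lasts
   only a few times the sudden bound);
3. reciprocal: within 1 s of onset the Assessment rate falls to ≤ 40% of
   its trial maximum;
4. Flight firing sustained ≥ 1 s but back inside the baseline band
   (inter-trial mean + 2 SD) before the trial ends;
5. Assessment stays inside its baseline band after Flight stops.

Sudden-transition times are measured on the raw PSTH with
persistence-based level crossings (a level counts as crossed only when it
holds for 3 consecutive bins), which rejects single-bin noise without the
~0.25 s bias a moving average would add; gradual envelopes are measured on
a ~1 s moving average. A non-Switch trial with at least two reciprocal
onset events separated by a reversal is **Intermittent** (events are only
counted when the smoothed Flight rate at least doubles its baseline, so
noise never registers); anything else is **None**. A multi-trial run is a
Switch when ≥ 80% of its trials are.

All constants are exposed in `classification_constants()` and are artifact
operationalizations of qualitative criteria, not published values.

## Latency and thresholding

For each trial with an onset, the latency runs from the moment the
approach ramp exceeds the 40 Hz baseline floor (`f_baseline/slope` seconds
into the trial) to the onset. Sensory thresholding predicts an inverse
latency–slope relation and a low dispersion of the input rate at onset;
`latency_analysis()` reports the Spearman correlation and the
coefficient of variation. The hard-threshold oracle — an `ideal-switch`
fixture whose constructed onset sits exactly where the ramp crosses a
chosen threshold — gives ρ = −1 and constant input-at-onset to < 1%, which
pins down the analysis arithmetic independently of any simulation.

## Synthetic fixtures

`make_fixture()` builds spike records with known classification outcomes
(ideal-switch, oscillating-reciprocal, silent, baseline-only) from
piecewise-linear rate profiles, one independent Poisson stream per neuron.
They emulate the *categories* — clean collapse, repeated reversals, no
structure — not the texture of simulated data: no gamma-band fluctuations,
no cross-neuron correlations, no slow drifts. Passing the classifier on
fixtures therefore shows the criteria are implemented as stated; the
simulated-circuit tests show they behave on realistic traces.

## Problem sizes used in the shipped tests

The test suite runs the full representative model 1 session (10 trials,
258 s) and single- or two-trial sessions elsewhere; latency analyses use
four slopes × two network realizations × two trials per model. Sweep
examples use one-trial-per-run sessions as in the original parameter
exploration. These sizes keep the whole suite within a few minutes on one
CPU while still exercising every claim end to end.

## Known limitations

* All unprinted constants are calibrated, not published; quantitative
  region boundaries (e.g. the stable τ_rebound interval) will differ from
  the original figures, and only the qualitative structure is asserted.
* Model 4's stable-Switch region is weaker under our defaults (see above).
* The rebound relay reproduces the intermediate population's transfer
  function but not any spike-threshold nonlinearity such units might have.
* Background noise enters as spike events with a calibrated weight; the
  original noise weight is unknown.
* No feedforward inhibition, neuromodulation, or Assessment−/Flight− cell
  classes are modeled.
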