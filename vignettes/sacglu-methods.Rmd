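---
title: "From glutamate imaging to direction selectivity: models and methods in sacglu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From glutamate imaging to direction selectivity: models and methods in sacglu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacglu)
```

## The scientific problem

Starburst amacrine cells (SACs) compute motion direction in their
dendrites. The space-time wiring hypothesis holds that bipolar cells (BCs)
with *sustained* release kinetics contact proximal SAC dendrites while
*transient* BCs contact distal dendrites, so that a bar moving from the
soma towards the dendritic tips (centrifugal motion) lines up slow and
fast excitation at the dendritic tip, while centripetal motion de-aligns
them. `sacglu` implements the complete analysis chain needed to evaluate
this hypothesis from fluorescent glutamate-sensor (iGluSnFR) recordings:

1. **Trace kinetics** — ΔF/F, SNR-based ROI selection, the
   sustained/transient index (STi), rise time, latency, and
   reverse-correlation kernels with biphasic indices.
2. **Release inference** — temporal (Fourier) deconvolution of ΔF/F
   against a quantal waveform, quantal amplitude from steady-state
   fluctuation analysis, Poisson discretisation into single-vesicle
   trains, and reconvolution as a self-check.
3. **A compartmental SAC model** — a ball-and-stick passive cable driven
   by kinetically distinct vesicle trains, with a terminal Ca²⁺ readout
   and a direction-selectivity index (DSi).
4. **A synthetic-data generator** that produces traces with exactly the
   statistical structure the analysis assumes, with ground truth attached.

## Trace kinetics

ΔF/F is `(F - F0)/F0` with `F0` the mean raw fluorescence in the 1 s
before stimulus onset. SNR is the peak ΔF/F in the stimulus window over
the baseline ΔF/F standard deviation; only ROIs with SNR > 4 (strict) pass
the default filter. STi is the plateau/peak ratio, with the plateau window
defaulting to the last 1 s of the stimulus: STi = 0 is purely transient,
STi = 1 purely sustained. Negative plateaus are reported as-is (no
clipping), so STi can be negative for suppressive responses; the
0 ≤ STi ≤ 1 guarantee holds whenever ΔF/F is nonnegative and the plateau
window lies inside the peak window.

Conventions the underlying measurements leave open, fixed here and
configurable: the "80–20 %" rise time is the 20 % → 80 % rising-phase
interval with linear interpolation between samples; latency is the time
from stimulus onset to the first upward crossing of 20 % of peak. The
reverse-correlation kernel is a 1-D cross-correlation of the response
against the centred contrast stimulus, normalised by the stimulus variance
(so a response generated by convolution recovers the generating filter in
expectation) and displayed on a 0.5-centred contrast scale. The biphasic
peak index is `Trough/(Peak + Trough)` and the biphasic area index is
`-negative/(positive - negative)`, where per-sample deviations from 0.5
are clamped to [−1, 1]; the printed source formulas are typographically
ambiguous, and this clamp-and-ratio reading makes both indices land in
[0, 1] with 0 for purely positive kernels.

## Release inference

A single released vesicle produces a stereotyped ΔF/F transient, modelled
as a peak-normalised double exponential with 2 ms rise and 30 ms decay
(an alpha-function form is available; with rise ≪ decay the two are
numerically close). Because imaging frames integrate fluorescence over the
frame period, `sample_quantum()` returns *frame-averaged* waveforms: each
sample is the mean of the continuous waveform over its frame. This
conserves the waveform integral at any frame rate and removes the
sampling-phase aliasing a point-sampled 2-ms-rise template would suffer at
~58 Hz.

**Quantal amplitude.** For a Poisson superposition with rate *r* and
frame-averaged unit template *q̄*, Campbell's theorem gives steady-state
mean `r A S1` and variance `r A² S2` with `S1 = ∫q̄` and `S2 = ∫q̄²`. The
classical quantal size estimate `QSE = 2σ²/µ` (implemented literally in
`estimate_qse()`) equals `A` exactly when `S2/S1 = 1/2`, i.e. for a pure
exponential decay. For the double-exponential frame-averaged template the
ratio differs, so the pipeline's default is the shape-corrected estimator
`A = (σ²/µ)·S1/S2` (`calibrate_quantum_amplitude()`). At the defaults
(~1–6 vesicles in a 1-s steady window per ROI) single-ROI fluctuation
statistics are extremely heavy-tailed and the amplitude's reciprocal
enters the rate estimate, so `infer_release()` pools `Σσ²/Σµ` across all
ROIs by default — the amplitude is a property of the sensor, not of the
response class — with `"group"` and `"per_roi"` modes for data with
heterogeneous indicator expression.

**Deconvolution.** The release rate is
`IFFT(FFT(response)·Q*/(|Q|² + ε·max|Q|²)·G(f))/dt` with ε = 1e-3
(Wiener stabilisation; naive spectral division is noise-amplifying) and
`G(f) = exp(-½(f/f_c)²)` a Gaussian low-pass with `f_c` = 20 Hz, unity at
DC. A Gaussian was chosen over a brick-wall cutoff because its impulse
response is nonnegative: the deconvolved vesicle train then stays
essentially nonnegative and rectification (negative excursions set to
zero; the raw estimate is kept alongside) does not inflate the mean rate.
Traces are mean-padded to the next power of two before the FFT and
trimmed afterwards. DC gain is `1/(1+ε)`, so the rate integral matches
(response integral)/(quantum integral) to 0.1 % on clean data.

Two systematic effects remain and are worth knowing about. ΔF/F
referencing measures fluorescence relative to a baseline that itself
contains spontaneous release, so the deconvolved rate is offset downward
by roughly the spontaneous rate. And under measurement noise the
rectified rate acquires a positive floor of order 0.4·(noise s.d. in rate
units) in quiet stretches. At the generator defaults these contribute
roughly −0.2 and +0.5 vesicles/s respectively to both groups; group-mean
steady-state estimates land near 3.3 vesicles/s for the sustained group
(true 3) and the sustained/transient ratio near 2.5 (true 3), both within
the ±25 % recovery tolerance the package tests enforce.

**Discretisation.** `discretize_poisson()` draws independent Poisson
counts in 1-ms bins with mean rate·bin and places events at bin centres;
`reconvolve()` superposes one frame-integrated quantum per event (or
convolves a continuous rate) so that deconvolve → reconvolve reproduces a
noiseless trace up to the regularisation bandwidth (r ≥ 0.99 without the
low-pass, r ≥ 0.95 with it).

## The compartmental model

**Geometry and membrane.** One spherical somatic compartment (8 µm) plus
three dendritic sections — initial 0–40 µm × 0.9 µm, middle
40–110 µm × 0.4 µm, terminal 110–150 µm × 0.3 µm — at 2 µm spatial
resolution; Cm 1 µF/cm², Rm 20 kΩ·cm², Ra 100 Ω·cm, leak reversal
−60 mV. The published model this emulates defers its exact channel
complement and passive values to source data not reproduced in the text,
so these are explicit stand-ins, all exposed in `sac_morphology()` /
`sac_config()`. The cable equation is integrated by a backward-Euler
scheme (compiled code) with the synaptic conductance entering the matrix
implicitly, so the solver is unconditionally stable even for the 0.54-ms
AMPA decay; the default 0.025-ms step resolves that decay with <1 %
error under step halving, and the solver reproduces the analytic
sealed-end finite-cable steady state to <1 %.

**Synapses.** Six proximal and twelve distal synapses per trial are drawn
from truncated-Gaussian placement densities (proximal mean 25 µm, s.d.
10 µm on [5, 45]; distal mean 75 µm, s.d. 20 µm on [45, 145]) standing in
for connectomic position distributions; user-supplied densities replace
them via `sac_config()`. Each vesicle triggers a double-exponential
conductance (rise 0.14 ms, decay 0.54 ms, reversal 0 mV) whose peak is
scaled linearly with distance from 172.2 pS at 5 µm to 68.6 pS at 145 µm.
AMPA events sum linearly — no saturation or desensitisation.

**Stimulus and release.** A 400-µm bar sweeps the 1-D dendritic axis at
0.1–2 mm/s; a synapse activates when the bar's leading edge reaches its
60-µm receptive field and deactivates when the trailing edge clears it,
so every synapse is active for `(bar + RF)/velocity` seconds. During
activation a sustained synapse releases at the canonical sustained
profile (onset peak 8 vesicles/s decaying with τ = 0.15 s to a 3 vesicles/s
plateau held until offset); a transient synapse decays to a 1 vesicle/s
plateau. Trains are drawn in 1-ms Poisson bins *in activation-locked
time*, so one seed replays the same vesicle sequence for both motion
directions and paired-direction DSi contrasts are not diluted by
independent shot noise.

**Readout.** Terminal Ca²⁺ is a first-order pool
(`dCa/dt = k·(-I_Ca) - Ca/τ`, τ = 50 ms) fed by a Boltzmann-activated
high-voltage Ca conductance (half-activation −30 mV, slope 6 mV,
instantaneous activation) pooled over the whole terminal dendritic
section — terminal Ca accumulation, not a point measurement, so single
minis adjacent to one compartment do not dominate the peak. Ca is in
arbitrary units and the conductance does not feed current back into the
voltage equation; DSi uses peaks only. DSi defaults to the subtraction
reading, `peakCa(centrifugal) − peakCa(centripetal)` (positive =
centrifugal preference); the normalised index `(CF−CP)/(CF+CP)` is
reported alongside. Peak Ca is averaged over `n_trials = 3` presentations
per direction before DSi is formed, as experimental DSi values are
computed from trial-averaged responses.

**What the model shows, and its limits.** With the stand-in passive
parameters, depolarisations are a few millivolts and the kinetic
space-time effect on DSi is real but small: the mean DSi is positive for
the native arrangement at every velocity tested, strongest near
0.25 mm/s; swapping the kinetics reverses the preference (negative mean
DSi); and incrementally converting sustained inputs to transient ones at
0.15 mm/s walks the mean DSi down approximately linearly from the native
value to slightly negative. Two published features of the original
(active-channel) model do **not** reproduce under these passive
stand-ins, and the package reports them as it finds them rather than
forcing agreement. First, an all-sustained dendrite does not sit neatly
between native and swapped: the conductance gradient plus asymmetric
cable geometry impart an intrinsic centripetal tendency when every input
is sustained. Second, the per-roster DSi magnitude shows essentially no
linear dependence on the proximal–distal synapse centroid distance
(R² ≈ 0.01 even with shot noise suppressed): in this passive regime the
long co-activation window at slow velocities makes DSi depend on local
features near the terminal rather than on group centroids. Shot noise in
the vesicle trains produces wrong-sign individual repeats at a ~20–30 %
rate, so directional claims are made about the mean over repeats (95 %
one-sided confidence), not about every single roster. An active dendrite
(regenerative Ca or other voltage-gated channels, not modelled because
their parameters are unpublished) would be expected to amplify both the
mean effect and its dependence on synapse placement.

## The synthetic-data generator

`synthesize_trace()` builds exactly what the inference assumes: an
inhomogeneous Poisson train from a canonical release profile on a 1-kHz
clock, one quantal waveform per vesicle (amplitude 0.5 ΔF/F per vesicle
by default, a typical single-event sensor amplitude), frame integration
down to 58.25 Hz, and additive Gaussian frame noise (0.01 ΔF/F s.d.
default; the sensor's true noise magnitude is not characterised in the
source measurements, so this is a free generator parameter chosen to give
comfortably filter-passing ROIs). Raw fluorescence is `F0·(1 + ΔF/F)`
with F0 = 100 a.u. so the ΔF/F step is exercised like real data. The
stimulus runs 4–6 s in an 8-s record. The onset-transient decay
τ = 0.15 s is a tuning chosen so sustained and transient STi separate
cleanly; it is not a measured value.

What the generator does **not** emulate: spatial image structure (ROIs are
generated directly, though `extract_rois()` handles grid tiling of real
stacks), sensor saturation and indicator nonlinearity, bleaching, and
trial-to-trial adaptation. One consequence worth stating: at realistic
per-ROI release rates (~1–3 vesicles/s) a trace is a sparse sequence of
single-quantum peaks, so synthetic STi magnitudes (~0.05–0.1) are smaller
than experimentally reported population values (~0.2–0.35) even though
their proximal/distal ordering and separation are preserved; passing
tests demonstrate the ordering and the recovery of generator parameters,
not the absolute experimental STi scale.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 100–250 synthetic ROIs
per kinetics group for release-rate recovery (the recovery tolerance is
±25 %); 64 rosters × 3 trials/direction for the directional sign checks
at 0.15 mm/s; 8 rosters for the incremental-conversion curve; and 100
rosters × 6 trials/direction at 0.25 mm/s (this configuration's
strongest-DSi velocity) for the DSi–distance regression. Ties and
degenerate inputs error loudly rather than guessing: non-monotonic time
axes, non-positive baselines, zero-variance baselines ("degenerate
baseline"), non-positive peaks ("no response"), flat kernels, zero-mass
placement densities, and negative rates passed to the Poisson
discretiser are all hard errors. All randomness flows through explicit
seeds; one master seed reproduces any run bit-for-bit.
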