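# sacglu

Glutamate input kinetics and direction selectivity in starburst amacrine
cell (SAC) dendrites.

Retinal direction selectivity is thought to arise in part from
*space-time wiring*: bipolar cells with slow, **sustained** glutamate
release contact proximal SAC dendrites while fast, **transient** bipolar
cells contact distal dendrites, so that motion from the soma towards the
dendritic tips (centrifugal) sums excitation optimally at the dendritic
tip. `sacglu` implements the full computational chain needed to test this
idea from fluorescent glutamate-sensor (iGluSnFR) recordings:

* **Trace kinetics** — ΔF/F against a pre-stimulus baseline; ROI
  selection by signal-to-noise ratio, `SNR = peak ΔF/F / sd(baseline)`,
  keeping ROIs with SNR > 4; the sustained/transient index
  `STi = ΔF/F(plateau) / ΔF/F(peak)` (0 = purely transient, 1 = purely
  sustained); 20–80 % rise times and latencies; reverse-correlation
  temporal kernels with biphasic peak and area indices.
* **Vesicle release inference** — Fourier deconvolution of the response
  against an idealised quantal waveform (2 ms rise, 30 ms decay),
  `RR = IFFT(FFT(Response)/FFT(Quantum))`, stabilised by Wiener
  regularisation and a Gaussian low-pass; quantal amplitude from
  steady-state fluctuations (`QSE = 2σ²/µ`, Campbell's theorem);
  discretisation of rates into Poisson single-vesicle trains;
  reconvolution as a self-check.
* **A compartmental SAC model** — a ball-and-stick passive cable (soma +
  initial/middle/terminal dendrite) driven by kinetically distinct
  bipolar-cell vesicle trains scheduled by a moving bar; AMPA miniature
  events (0.14/0.54 ms, 0 mV reversal, 172.2→68.6 pS along the
  dendrite); terminal Ca²⁺ readout and a direction-selectivity index
  `DSi = peakCa(centrifugal) − peakCa(centripetal)`; velocity sweeps,
  kinetics-swap, incremental-conversion and DSi-versus-synapse-distance
  experiments.
* **A synthetic-data generator** — Poisson vesicle trains convolved with
  quantal waveforms, frame-integrated and noise-corrupted, with ground
  truth attached, so every stage is testable without any recording.

## Worked example

```r
library(sacglu)

# synthesise a field of view: 20 sustained (proximal) and 20 transient
# (distal) ROIs at the default release profiles (plateaus 3 and 1
# vesicles/s)
fov <- synthesize_fov(20, 20, seed = 42)
fov <- compute_dff(fov)

kin <- analyze_kinetics(fov)
aggregate(cbind(sti, snr) ~ group, kin[kin$passed_filter, ], mean)
#>      group        sti      snr
#> 1   distal 0.04549944 37.42768
#> 2 proximal 0.08274081 48.78517

# infer vesicle release rates by deconvolution
inf <- infer_release(fov, roundtrip = TRUE)
aggregate(cbind(steady_rate_vps, roundtrip_r) ~ group, inf$table, mean)
#>      group steady_rate_vps roundtrip_r
#> 1   distal        1.51810    0.9684020
#> 2 proximal        3.25282    0.9870165
```

The proximal (sustained) group recovers a steady-state rate near its
generating 3 vesicles/s plateau and clearly separates from the distal
(transient) group, mirroring the proximal/distal release-rate gradient
along SAC dendrites; `roundtrip_r` is the correlation between each trace
and the reconvolution of its estimated release rate with the quantal
waveform. STi values separate in the expected direction (sustained >
transient); their absolute scale is set by single-quantum peaks at these
low rates (see the methods vignette).

```r
# one starburst simulation pair and its direction selectivity
cfg <- sac_config()
roster <- sample_synapse_locations(seed = 1)
pair <- simulate_bar_pair(cfg, roster, velocity_mm_s = 0.25, seed = 1)
pair$dsi        # > 0: centrifugal preference
```

A command-line interface wrapping the same functions is installed at
`inst/cli/sacglu` with subcommands `generate`, `analyze-kinetics`,
`infer-release` and `simulate-ds`.

## Package layout

* `R/trace-io.R` — ROI trace containers, CSV/container I/O, ΔF/F, ROI
  grid extraction from image stacks
* `R/kinetics.R`, `R/kernels.R` — kinetics metrics and
  reverse-correlation kernels
* `R/quantum.R`, `R/release.R` — quantal waveform fitting, fluctuation
  analysis, deconvolution, Poisson trains
* `R/sac-model.R`, `R/sac-experiments.R`, `src/cable.cpp` — the
  compartmental model (implicit cable solver in C++) and its experiments
* `R/synthetic.R` — the synthetic-data generator
* `R/cli.R`, `inst/cli/sacglu` — command-line entry points
* `vignettes/sacglu-methods.Rmd` — models, assumptions, parameter
  defaults and limitations
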