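Package: sacglu
Title: Glutamate Input Kinetics and Direction Selectivity in Starburst
    Amacrine Cell Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fluorescent glutamate-sensor (iGluSnFR)
    recordings along retinal starburst amacrine cell dendrites and for
    testing the space-time wiring model of direction selectivity.
    Implements trace-kinetics metrics (signal-to-noise ratio filtering,
    sustained/transient index, rise time, latency, reverse-correlation
    kernels with biphasic indices), Fourier deconvolution of vesicle
    release rates against a fitted quantal waveform with fluctuation-based
    quantal size estimation and Poisson discretisation, a synthetic-data
    generator producing Poisson shot-noise traces with known ground truth,
    and a compartmental ball-and-stick starburst simulator driven by
    kinetically distinct bipolar-cell vesicle trains, with a terminal
    calcium direction-selectivity readout and velocity-sweep, kinetics-swap
    and incremental-conversion experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    optparse,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
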