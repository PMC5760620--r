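Package: jonadapt
Title: Mean and Variance Adaptation in Drosophila Auditory Receptor Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for studying how auditory receptor
    neurons in the Drosophila antenna (Johnston's organ neurons) adapt to the
    mean (baseline antennal deflection) and variance (sound intensity) of
    their mechanical input. Provides seeded synthesis of auditory stimuli
    (band-limited noise with intensity schedules, sinusoids, Gabor pulse
    trains, smoothed step deflections, composite mean/variance protocols);
    an adaptation-network model built from subtractive and divisive
    incoherent feedforward loops interleaved with rectification, with full
    intermediate-signal traces; exhaustive enumeration, functional
    deduplication and evaluation of all serial and two-branch parallel
    arrangements of these computations; regular and adaptive leaky
    integrate-and-fire population simulators; and the accompanying analysis
    chain (analytic-signal amplitude, exponential transient fits, onset and
    steady-state tuning curves, sigmoid fits, adaptation strength, Fisher
    information, tuning-curve shift regression), exercisable end to end on
    surrogate recordings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
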