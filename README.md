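# jonadapt

Mean (offset) and variance (intensity) adaptation in the auditory receptor
neurons of *Drosophila* — the Johnston's organ neurons (JONs) in the
antenna. The antenna is deflected slowly by wind and gravity (the **mean**
of its displacement distribution) while courtship song vibrates it at
100–350 Hz with an intensity — particle velocity, mm/s — equal to the
**standard deviation** of those vibrations. Faithful song encoding
requires subtractive correction for the mean and divisive correction for
the variance, within a single receptor neuron, and without the first
correction degrading sound sensitivity.

The package implements the computational core of that account for anyone
modeling early sensory gain control:

* **Adaptation network.** Elementary computations — subtractive and
  divisive incoherent feedforward loops (leaky-integrated adaptation
  signal with time constant τ opposing the input) plus half/full-wave
  rectification — composed into serial or two-branch parallel networks,
  with every intermediate signal recorded. The canonical model is the
  serial chain

  subtract (τ_sub = 30 ms) → full-wave rectify → divide (τ_div = 50 ms),

  with the divisive stage `x / (c + x_ada)`, `c = 2e-6 / σ_div`
  (σ_div = 1e-4). Rectification converts stimulus variance into signal
  mean — enabling divisive intensity adaptation and doubling the
  frequency of tonal carriers — and its placement after mean subtraction
  is what keeps sound sensitivity independent of antennal offset.
* **Motif search.** Exhaustive enumeration of the network grammar
  (72 serial and 576 parallel slot assignments), functional
  deduplication on a stimulus battery, and evaluation of every class
  against four adaptation paradigms with CV-based selection: exactly one
  class — the subtract → rectify → divide chain — reproduces the
  experimental adaptation pattern.
* **Stimuli.** Seeded band-limited noise (80–1000 Hz) with intensity
  schedules, every-ordered-transition noise steps, background/probe
  protocols, sinusoids, Gabor pulse trains (36 ms inter-pulse interval),
  smoothed step deflections and composite offset+sine protocols.
* **Analysis chain.** Analytic-signal (Hilbert) amplitude, exponential
  transient fits r(t) = r0 + rmax·exp(−t/τ), onset/steady tuning curves
  (8/10 ms windows), sigmoid fits
  r(x) = r0 + rmax/(1 + exp(−α(x−β))), adaptation strength
  1 − s_ss/s_on, Fisher information (dr/dx)²/r, and tuning-shift
  regression on log2 background.
* **LIF population controls.** Regular and adaptive leaky
  integrate-and-fire populations (Euler, 1/20 ms) under
  independent/shared/range-fractionation stimulus policies, to separate
  genuine firing-rate adaptation from synchrony or heterogeneity
  explanations of compound signals.
* **Surrogate recordings.** Multi-trial raw-signal proxies with known
  ground-truth envelopes, frequency-doubled carriers and
  variance-proportional-to-mean trial noise, so the whole pipeline is
  testable without experimental data.

## Worked example

Divisive variance adaptation, measured exactly as in the
background/probe experiments — intensity tuning curves under five noise
backgrounds, sigmoid fits, shift regression and Fisher-information
peaks — averaged over five frozen-noise replicates of 40 probe
repetitions:

```r
library(jonadapt)
va <- variance_adaptation_analysis(seed = 1)
round(c(slope = va$shift_slope, r2 = va$shift_r2,
        fisher_max_dev = va$fisher_max_dev), 3)
#>          slope             r2 fisher_max_dev
#>          0.928          1.000          0.180
```

The tuning curves shift 0.93 octaves per octave of background intensity
(slope 1 = complete divisive adaptation, "the diagonal") with r² > 0.999,
and the Fisher-information peak — the intensity region of maximal
discriminability — stays within 0.18 octaves of every background:
adaptation keeps discrimination centered on the current background.

The motif search that singles out the canonical chain:

```r
ser <- enumerate_serial()           # 72 raw -> 42 structural classes
dd  <- dedup_functional(ser, motif_battery(seed = 1))   # -> 33 functional
proto <- eval_protocol(seed = 1, n_reps = 6)
ev <- evaluate_motif(network_motif(serial = c("S", "R", "D")), proto)
ev$pass
#> [1] TRUE
```

and the frequency doubling that betrays full-wave rectification:

```r
b <- run_experiment(experiment_config("fig3_song", seed = 1))
b$summary$doubling_freq_hz
#> [1] 600
```

`run_experiment()` exposes the figure-level experiments
(`fig1_steps`, `fig2_background_probe`, `fig3_song`, `fig5_interaction`,
`fig6_model`, `motif_search`, `lif_controls`); `write_outputs()`
serializes any result bundle to CSV + JSON. The methods vignette
(`vignettes/adaptation-model.Rmd`) documents the model, the protocol
design and its numerical choices.

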