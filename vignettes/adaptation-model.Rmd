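---
title: "Mean and variance adaptation in fly auditory receptor neurons: the model and its analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean and variance adaptation in fly auditory receptor neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jonadapt)
```

## The scientific problem

The auditory receptor neurons of *Drosophila* (Johnston's organ neurons,
JONs) transduce the mechanical displacement of the antenna. That
displacement has two independent components: a slowly varying baseline set
by wind and gravity (the **mean** of the displacement distribution) and
sound-induced oscillations whose standard deviation is the sound
**intensity** (particle velocity, mm/s). Faithful encoding of courtship
song therefore requires two corrections inside one neuron — subtractive
adaptation to the baseline and divisive adaptation to the intensity — and
the corrections must not interfere: a deflected antenna should not change
sound sensitivity.

This package implements the computational account of how that separation
can be achieved, along with everything needed to exercise it: stimulus
synthesis, exhaustive search over alternative arrangements of the
elementary computations, leaky integrate-and-fire (LIF) population
controls, and the tuning-curve/Fisher-information analysis chain, all
testable on surrogate data with known ground truth.

## The adaptation network

Each adaptation stage is an incoherent feedforward loop: the input is
low-pass filtered by leaky integration (unit-area exponential kernel,
time constant $\tau$) into an adaptation signal $x_{\mathrm{ada}}$ that
opposes the input, either subtractively,

$$x_{\mathrm{out}} = x_{\mathrm{in}} - x_{\mathrm{ada}},$$

or divisively,

$$x_{\mathrm{out}} = \frac{x_{\mathrm{in}}}{c + x_{\mathrm{ada}}},
\qquad c = \frac{2\times10^{-6}}{\sigma_{\mathrm{div}}}.$$

Rectification (full-wave $|x|$ by default, half-wave optional) is the
third elementary computation. The canonical model is the serial chain

$$\text{subtract} \;\rightarrow\; \text{rectify} \;\rightarrow\;
\text{divide}$$

with $\tau_{\mathrm{sub}} = 30$ ms, $\tau_{\mathrm{div}} = 50$ ms and
$\sigma_{\mathrm{div}} = 10^{-4}$. The logic: the subtractive loop's
adaptation signal tracks only slow, mean-like components (for symmetric
sound-frequency oscillations it is nearly flat), so the first stage
removes the baseline without touching the sound. Full-wave rectification
then converts the signal's standard deviation into its mean — which is
what lets a second, divisive loop normalize for intensity, and which
doubles the frequency of a tonal carrier (a 300 Hz tone drives a 600 Hz
output component). Because the rectified step responses also have nonzero
mean, divisive adaptation reduces step sensitivity: the interaction
between the two forms of adaptation is unidirectional, exactly as
observed physiologically.

### The divisive denominator constant

The denominator constant deserves a note, because it carries all of the
model's absolute intensity scale. $\sigma_{\mathrm{div}}$ controls the
completeness of adaptation through an *inverse* floor
$c = 2\times10^{-6}/\sigma_{\mathrm{div}}$: when the adaptation signal
dominates $c$, the output approaches the fully normalized ratio
$x/x_{\mathrm{ada}}$; when $\sigma_{\mathrm{div}}$ is small enough that
$c$ swamps $x_{\mathrm{ada}}$, the stage degenerates to a fixed gain and
adaptation disappears. At the default, $c = 0.02$ in stimulus units —
at the lower edge of the 0.1–1 mm/s dynamic range of the auditory
neurons — so divisive adaptation is essentially complete over the
behaviorally relevant range (backgrounds 1/4–4 mm/s) while tuning curves
measured against silence remain graded rather than perfectly
self-normalized. The constant also keeps the gain finite in silence. It
is deliberately independent of $\tau_{\mathrm{div}}$, so that robustness
sweeps over time constants change only dynamics, not operating range.

```{r divisive-fixed-point}
# steady state of the divisive stage for constant input c = 1
sapply(c(1e-8, 1e-4, 1), function(sg)
  tail(divide_stage(rep(1, 20000), 0.05, sg)$out, 1))
```

## Stimuli

All stimuli are sampled at 10 kHz and generated bit-reproducibly from a
seed. Band-limited Gaussian noise (80–1000 Hz, linear-phase FIR with
group-delay compensation, rescaled to unit SD) is the workhorse; its
intensity is its standard deviation, while sinusoids and Gabor pulse
trains use the peak-amplitude convention (the field quotes single mm/s
values for tones). Intensity schedules switch the noise SD in blocks with
a 1 ms linear crossfade of the scale factor; the noise-step protocol
visits every ordered pair of intensities via an Eulerian circuit over the
complete transition digraph. Pulse trains are sums of Gabor wavelets
(250 Hz carrier, 4.6 ms envelope SD, 36 ms inter-pulse interval by
default — the conspecific song pulse), and composite mean/variance
protocols superimpose static offsets (µm) and 300 Hz sinusoids, with
velocity and displacement amplitudes related by $v = 2\pi f d$.

## Motif search

The generating grammar for serial networks fills five slots
(R/∅ → S/D/∅ → R/∅ → S/D/∅ → R/∅), giving 72 raw assignments; two-branch
parallel networks (input node, two three-slot branches, output node,
branch outputs summed sample-wise) give 576. Because "uniqueness" of such
networks has no canonical definition, the package uses functional
equivalence as the arbiter: two motifs are equivalent when their outputs
agree within $10^{-6}$ (inputs are O(1)) on a battery of tones, signed
steps, noise-intensity steps and offset+tone composites, with structural
canonicalization (drop empty nodes, collapse adjacent rectifiers, order
branches) as a fast pre-pass. This yields 42 structural / 33 functional
serial classes and 140 structural / 64 functional parallel classes. The
counts quoted for this grammar in the experimental literature (22 serial,
100 parallel) evidently rest on a different, unstated equivalence; the package reports
the raw, structural and functional counts side by side rather than
forcing agreement. Note one corner the grammar produces: the all-empty
parallel network sums two identity branches and is therefore a doubler,
not the identity.

Every deduplicated motif is scored against four adaptation paradigms
mirroring the experimental designs:

1. step tuning under offset adaptation (probe steps around an adapted
   offset, curves compared on the offset-relative axis);
2. intensity tuning under noise-background adaptation (noise probes on
   noise backgrounds 1/4–4 mm/s, log2 axis, compared background-relative);
3. intensity tuning under offset adaptation (300 Hz probes, absolute
   axis);
4. step tuning under sustained 300 Hz stimulation of different
   intensities (absolute axis).

Each condition's tuning curve is fitted with the sigmoid
$r(x) = r_0 + r_{\max}/(1+e^{-\alpha(x-\beta)})$, and each paradigm is
summarized by dispersions across adaptation conditions: `cv_shift`
(SD of $\beta$ on the comparison scale, normalized by the probe-axis
range — a scale-free dispersion that stays defined when the mean shift is
zero), `cv_slope` (SD/|mean| of the curve slope: the fitted maximal slope
$r_{\max}\alpha/4$ for intensity curves, the chord slope for the
near-linear step curves, whose four-parameter fits are ridge-unstable),
and `cv_offset` (SD of $r_0$ over mean $r_{\max}$). A data-consistent
motif needs small shift and slope dispersion in paradigms 1–3 and, in
paradigm 4, a small *vertical offset* dispersion together with a high
slope dispersion: the recordings show step-tuning position shifting with
the background-sine intensity (so position invariance cannot be the
criterion there), while the baseline stays put and the slope carries the
divisive gain change. With the default thresholds (small < 0.1,
high > 0.5) exactly one functional class survives: the serial
subtract → rectify → divide chain. Reversing the adaptation order or
omitting rectification fails, the latter because a divisive loop fed a
zero-mean signal has no adaptation signal to divide by.

## How model responses are measured

The model's output is an envelope-like non-negative signal, so a probe
"response" is its time average over a window — and the window choice is
consequential, because the model, unlike the physiological compound
action potential, has no output saturation:

* **Sustained intensity probes** (noise or sine) are measured over
  0.30–0.65 $\tau_{\mathrm{div}}$ after probe onset. Windows that include
  the onset produce non-saturating curves (the first output samples are
  divided by the still-unadapted denominator and grow without bound in
  probe intensity), leaving the sigmoid position undefined. In the
  mid-adaptation window the probe-average adaptation fraction is about
  1/3, which places the curve midpoint one octave above the adapting
  background; the window end was chosen, by the same calculation extended
  with the denominator-constant correction at the softest background, so
  that the Fisher-information optimum (one logistic length constant below
  the midpoint) falls on the background itself. The probe set spans
  1/16–16 mm/s in octaves so every background's midpoint lies inside the
  probe axis.
* **Step probes** are transient by construction (the subtractive stage
  suppresses them within $\tau_{\mathrm{sub}}$) and are measured over the
  first 0.04 $\tau_{\mathrm{div}}$ (2 ms at the default), where the
  divisive state still reflects only the pre-probe background: step
  responses are then purely gain-scaled by the adaptation state.
* All protocol timescales — probe duration ($= \tau_{\mathrm{div}}$),
  ramps (0.02 $\tau_{\mathrm{div}}$, the experimental 1 ms at the
  default), step smoothing, recovery gaps (6 $\tau_{\mathrm{div}}$, plus
  5 $\tau_{\mathrm{sub}}$ for step paradigms whose probe offsets leave
  subtractive transients) and burn-in (15 max($\tau$)) — scale with the
  model's time constants, so parameter grids are probed under
  geometrically identical conditions.
* Step probes start above the largest background-sine displacement
  amplitude, outside the regime where full-wave rectification mixes probe
  and carrier nonlinearly.

For the quantitative variance-adaptation analysis
(`variance_adaptation_analysis()`), one frozen noise-carrier realization
is shared by all background conditions of a replicate, so
realization-specific fluctuations cancel exactly in cross-background
comparisons (common random numbers; freezing the noise across conditions
is also one of the study's own stimulus policies), and five independent
frozen-noise replicates of 40 probe repetitions — playing the role of the
five recorded animals at their 40-trial averages — are averaged at the
level of fitted parameters. Those fits fix $r_0 = 0$, the baseline the
model provably has, which removes the $r_0$–$\beta$ trade-off that
otherwise destabilizes position estimates.

```{r variance-adaptation, eval = FALSE}
va <- variance_adaptation_analysis(seed = 1)
va$shift_slope      # ~0.95: one octave of shift per octave of background
va$shift_r2         # > 0.999
va$fisher_devs      # per-background Fisher-peak deviation, log2 units
```

## LIF population controls

The proof-of-principle population models contrast the firing-rate
explanation of adaptive population dynamics with alternatives (synchrony,
response heterogeneity, range fractionation). The LIF is simulated
rest-relative (rest 0, threshold +1 mV, reset to rest, membrane
resistance 1) by Euler integration at 1/20 ms:
$\tau_V \dot V = I_{\mathrm{in}} - V - I_{\mathrm{adapt}}$, with the
adaptation current decaying with $\tau_{\mathrm{adapt}}$ and incrementing
by $\Delta A$ at each spike (the printed form of this differential
equation omits the decay sign; the decaying form is the only one that
produces spike-frequency adaptation). The stimulus scaling
$\sigma_{\mathrm{stim}} = 4.6$ is the output of the packaged calibration
routine (`calibrate_sigma_stim()`: 100 Hz steady rate at 1 mm/s noise).
Under a 1 → 2 → 1 mm/s noise-step protocol at n = 100 neurons and 20
trials, the adaptive population ($\Delta A = 1$ mV) produces a positive
population-rate transient at the increase and a negative transient at the
decrease, while the regular population tracks intensity with no
sustained-state transients — the signature that distinguishes genuine
rate adaptation from its population-level impostors. The compound-signal
proxy (PSTH convolved with a fixed biphasic kernel) is a stand-in; the
exact construction of the compound signal in the original population
analyses is not described.

## Surrogate recordings and recovery fixtures

`surrogate_cap()` turns any model trace into a multi-trial raw-recording
proxy: the model output is the ground-truth envelope riding on a carrier
at twice the dominant stimulus frequency (tonal case) or on the
band-passed stimulus itself (noise case), plus Gaussian trial noise whose
variance is proportional to the local envelope mean (`noise_gain`, default
0.02, chosen so 20-trial averages show the trial-to-trial spread typical
of single-preparation recordings). White Gaussian trial noise is an
assumption; the true single-trial noise spectrum of such recordings is
not modeled. Recovery fixtures provide exponential transients, sigmoid
curves and Fisher profiles with stored parameters; their default noise SD
(0.032 at unit response) is the 20-trial-average implied by the surrogate
noise model, and at that level the chain recovers $\tau$ within 20% and
$(\alpha, \beta)$ within 10%.

## Numerical choices and degenerate inputs

Leaky integration uses the exact exponential-hold recursion
(unconditionally stable; coefficient $e^{-\Delta t/\tau}$); the
subtractive stage therefore nulls DC exactly. The divisive denominator is
floored at $10^{-9}$ with a flag for arbitrary motifs whose signed
adaptation signals can cross zero (the canonical chain cannot reach this
regime). Sigmoid and exponential fits run Levenberg–Marquardt on the
residuals directly (`minpack.lm::nls.lm`) with deterministic
initialization and a fixed multi-start ladder on $\alpha$; model-frame
based fitting was found to fail spuriously on exactly interpolable
(noiseless) curves. Flat traces, non-convergent fits and zero onset
slopes are flagged, never fatal. When paradigm-3 tuning curves are fully
self-normalized (very large $\sigma_{\mathrm{div}}$) and thus unfittable,
offset invariance is judged by direct curve comparison: identical curves
across offsets mean zero shift.

## What the synthetic tests do and do not show

Everything here is exercised on synthesized stimuli and surrogate
recordings: passing tests show that the implementation realizes the
stated computations, that the canonical chain uniquely reproduces the
qualitative adaptation pattern *of the model framework*, and that the
analysis chain recovers known parameters at realistic noise. They cannot
show that real receptor neurons implement these computations, nor do the
surrogates reproduce real recording artifacts (electrode drift, movement,
non-Gaussian noise, spike-waveform structure). Problem sizes are scaled
for routine runs — 9 probes × 40 repetitions × 5 backgrounds for the
quantitative analyses, 5 × 5 time-constant grids with
reduced-but-noise-equalized averaging for robustness sweeps, n = 100
neurons × 20 trials for populations — and every scale is a function
argument.

## Known limitations

The divisive denominator constant is a reconstruction: the value quoted
in the experimental literature only yields the reported adaptation
behavior under a particular reading of the adaptation-signal
normalization and unit scale, and the package adopts the dimensionless
form that reproduces that behavior (see the
denominator section above). Motif-class counts depend on the equivalence
chosen; both raw and deduplicated counts are reported. The
Fisher-optimum tracking of the background is exact only up to the
denominator constant's residual effect at the softest background
(≈ 0.1–0.2 octaves) plus realization noise. Parallel-branch combination
is fixed to summation; motifs with more than two adaptation stages or
branches are out of scope, as are biophysical channel models and antennal
mechanics.
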