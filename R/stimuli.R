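#' Sampled mechanical stimulus
#'
#' Container for a sampled antennal stimulus waveform. Intensities follow the
#' conventions of the experiments this package models: for band-limited noise,
#' intensity is the standard deviation of the waveform; for sinusoids and
#' pulses it is the peak amplitude. Units are either particle velocity
#' (mm/s, sound stimuli) or displacement (um, static deflections of the
#' antenna).
#'
#' @param samples numeric vector of samples; must be finite.
#' @param sample_rate sampling rate in Hz (default 10000).
#' @param units `"velocity_mm_s"` or `"displacement_um"`.
#' @param schedule optional [intensity_schedule()] annotation.
#' @param seed integer seed used to generate the waveform, or `NULL`.
#' @param probes optional data frame of probe events (`onset_s`, `value`,
#'   `condition`) attached by protocol generators.
#' @return An object of class `"stimulus"`.
#' @export
stimulus <- function(samples, sample_rate = 10000,
                     units = c("velocity_mm_s", "displacement_um"),
                     schedule = NULL, seed = NULL, probes = NULL) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("stimulus samples must be finite")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(
    list(samples = samples, sample_rate = sample_rate, units = units,
         schedule = schedule, seed = seed, probes = probes),
    class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> %d samples @ %g Hz (%.3f s), units: %s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$units))
  if (!is.null(x$schedule))
    cat(sprintf("  schedule: %d segments, intensities %g..%g\n",
                nrow(x$schedule), min(x$schedule$intensity),
                max(x$schedule$intensity)))
  if (!is.null(x$probes))
    cat(sprintf("  probes: %d events\n", nrow(x$probes)))
  invisible(x)
}

#' Duration of a stimulus in seconds
#' @param stim a [stimulus()].
#' @return duration in seconds.
#' @export
stim_duration <- function(stim) length(stim$samples) / stim$sample_rate

#' Piecewise-constant intensity schedule
#'
#' Describes the target intensity of a noise carrier over time. At each
#' switch the scale factor is linearly interpolated over `ramp_duration`
#' (1 ms by default) to avoid broadband artifacts from abrupt intensity
#' changes.
#'
#' @param onsets numeric vector of segment onset times (s), strictly
#'   increasing, starting at 0.
#' @param intensities positive intensities (mm/s), one per onset.
#' @param ramp_duration crossfade duration at each switch (s).
#' @return A data frame of class `"intensity_schedule"` with columns
#'   `onset_s` and `intensity` and a `ramp_duration` attribute.
#' @export
intensity_schedule <- function(onsets, intensities, ramp_duration = 0.001) {
  stopifnot(length(onsets) == length(intensities), length(onsets) >= 1)
  if (any(diff(onsets) <= 0)) stop("schedule onsets must be strictly increasing")
  if (any(intensities <= 0)) stop("schedule intensities must be positive")
  if (length(onsets) > 1 && ramp_duration >= min(diff(onsets)))
    stop("ramp_duration must be shorter than the shortest block")
  out <- data.frame(onset_s = onsets, intensity = intensities)
  attr(out, "ramp_duration") <- ramp_duration
  class(out) <- c("intensity_schedule", "data.frame")
  out
}

# windowed-sinc band-pass FIR (odd length, linear phase); returns coefficients
fir_bandpass <- function(band, sample_rate, n_taps = 801) {
  nyq <- sample_rate / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop(sprintf("pass band must satisfy 0 < low < high < Nyquist (%g Hz)", nyq))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  signal::fir1(n_taps - 1, band / nyq, type = "pass")
}

# zero-phase band-pass: centred convolution with an odd-length linear-phase
# FIR compensates the group delay exactly (FFT-based for long inputs)
apply_fir <- function(x, b) {
  half <- (length(b) - 1) / 2
  n <- length(x)
  if (n > 20000) {
    # FFT convolution, zero-padded to a highly composite length
    N <- stats::nextn(n + length(b) - 1, c(2, 3, 5))
    Y <- stats::fft(c(x, numeric(N - n))) *
      stats::fft(c(b, numeric(N - length(b))))
    y <- Re(stats::fft(Y, inverse = TRUE)) / N
    return(y[(half + 1):(half + n)])
  }
  xp <- c(rep(0, half), x, rep(0, half))
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Band-limited Gaussian noise
#'
#' Gaussian white noise band-pass filtered with a linear-phase FIR filter
#' (group delay compensated) and rescaled to unit standard deviation, the
#' reference carrier to which intensity schedules are applied.
#'
#' @param duration duration in seconds.
#' @param band pass band `c(low, high)` in Hz; default 80--1000 Hz.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param sample_rate sampling rate, Hz.
#' @param n_taps FIR length (odd).
#' @return A unit-SD [stimulus()] in velocity units.
#' @export
bandlimited_noise <- function(duration, band = c(80, 1000), seed = NULL,
                              sample_rate = 10000, n_taps = 801) {
  stopifnot(duration > 0)
  b <- fir_bandpass(band, sample_rate, n_taps)
  n <- round(duration * sample_rate)
  x <- with_seed(seed, stats::rnorm(n))
  y <- apply_fir(x, b)
  y <- y / stats::sd(y)
  stimulus(y, sample_rate, "velocity_mm_s", seed = seed)
}

# per-sample scale envelope implementing a schedule with linear crossfades
schedule_envelope <- function(schedule, n, sample_rate) {
  ramp <- attr(schedule, "ramp_duration")
  if (is.null(ramp)) ramp <- 0.001
  starts <- round(schedule$onset_s * sample_rate) + 1L
  ends <- c(starts[-1] - 1L, n)
  env <- rep(schedule$intensity, times = pmax(ends - starts + 1L, 0L))
  length(env) <- n
  if (ramp > 0 && nrow(schedule) > 1) {
    nr <- round(ramp * sample_rate)
    for (k in 2:nrow(schedule)) {
      i0 <- starts[k]
      idx <- i0:min(i0 + nr - 1L, n)
      env[idx] <- schedule$intensity[k - 1] +
        (schedule$intensity[k] - schedule$intensity[k - 1]) *
        (seq_along(idx) - 1) / nr
    }
  }
  env
}

#' Apply an intensity schedule to a unit-variance noise carrier
#'
#' Scales each segment of the carrier to its target intensity (the target
#' standard deviation), crossfading the scale factor linearly over the
#' schedule's ramp duration at every switch. The schedule is attached to the
#' returned stimulus.
#'
#' @param stim a [stimulus()] with (approximately) unit standard deviation.
#' @param schedule an [intensity_schedule()] covering the stimulus duration.
#' @return A scheduled [stimulus()].
#' @export
apply_intensity_schedule <- function(stim, schedule) {
  stopifnot(inherits(stim, "stimulus"), inherits(schedule, "intensity_schedule"))
  dur <- stim_duration(stim)
  if (max(schedule$onset_s) >= dur)
    stop("schedule extends past the end of the stimulus")
  env <- schedule_envelope(schedule, length(stim$samples), stim$sample_rate)
  out <- stim
  out$samples <- stim$samples * env
  out$schedule <- schedule
  out
}

# Eulerian circuit over the complete digraph on k nodes (Hierholzer);
# returns a node sequence containing every ordered pair exactly once
eulerian_transitions <- function(k) {
  if (k == 1) return(1L)
  unused <- matrix(TRUE, k, k)
  diag(unused) <- FALSE
  path <- integer(0)
  stack <- 1L
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    nxt <- which(unused[v, ])
    if (length(nxt) > 0) {
      w <- nxt[1]
      unused[v, w] <- FALSE
      stack <- c(stack, w)
    } else {
      path <- c(v, path)
      stack <- stack[-length(stack)]
    }
  }
  path
}

#' Noise stimulus switching intensity through all ordered transitions
#'
#' Builds one continuous noise stimulus whose intensity schedule visits every
#' ordered pair of distinct intensities at least once as an adjacent
#' transition, switching every `block` seconds (100 ms by default, matching
#' the intensity-step protocol used to probe variance adaptation).
#'
#' @param intensities at least two intensities (mm/s); default the
#'   1/4, 1/2, 1, 2 mm/s set.
#' @param block block duration in seconds.
#' @param seed integer seed for the noise carrier.
#' @param band,sample_rate passed to [bandlimited_noise()].
#' @return A scheduled [stimulus()].
#' @export
protocol_noise_steps <- function(intensities = c(0.25, 0.5, 1, 2), block = 0.1,
                                 seed = NULL, band = c(80, 1000),
                                 sample_rate = 10000) {
  stopifnot(length(intensities) >= 2)
  seqn <- eulerian_transitions(length(intensities))
  vals <- intensities[seqn]
  onsets <- (seq_along(vals) - 1) * block
  sched <- intensity_schedule(onsets, vals)
  carrier <- bandlimited_noise(length(vals) * block, band, seed, sample_rate)
  apply_intensity_schedule(carrier, sched)
}

#' Background noise with interleaved probe segments
#'
#' Noise at a fixed background intensity, switched once per cycle to a probe
#' intensity for `probe_dur` seconds (defaults: 120 ms cycle, 20 ms probe,
#' matching the background--probe protocol used to measure intensity tuning
#' under adaptation). Probes cycle deterministically through `probes`.
#'
#' @param background background intensity (mm/s).
#' @param probes non-empty vector of probe intensities (mm/s); defaults to
#'   octave steps 1/16..8 mm/s.
#' @param cycle cycle duration (s).
#' @param probe_dur probe duration (s), `< cycle`.
#' @param n_cycles number of cycles; default one per probe.
#' @param seed,band,sample_rate noise carrier parameters.
#' @return A scheduled [stimulus()] with a `probes` table
#'   (`onset_s`, `value`).
#' @export
protocol_background_probe <- function(background, probes = 2^(-4:3),
                                      cycle = 0.120, probe_dur = 0.020,
                                      n_cycles = length(probes), seed = NULL,
                                      band = c(80, 1000), sample_rate = 10000) {
  if (length(probes) == 0) stop("probe list must not be empty")
  stopifnot(probe_dur < cycle, background > 0, all(probes > 0))
  probe_seq <- probes[((seq_len(n_cycles) - 1) %% length(probes)) + 1]
  onsets <- numeric(0)
  vals <- numeric(0)
  for (k in seq_len(n_cycles)) {
    t0 <- (k - 1) * cycle
    onsets <- c(onsets, t0, t0 + cycle - probe_dur)
    vals <- c(vals, background, probe_seq[k])
  }
  # collapse zero-length or redundant switches (probe == background)
  keep <- c(TRUE, diff(onsets) > 0 | diff(vals) != 0)
  keep <- keep & c(TRUE, vals[-1] != vals[-length(vals)])
  sched <- intensity_schedule(onsets[keep], vals[keep])
  carrier <- bandlimited_noise(n_cycles * cycle, band, seed, sample_rate)
  out <- apply_intensity_schedule(carrier, sched)
  out$probes <- data.frame(onset_s = (seq_len(n_cycles) - 1) * cycle +
                             cycle - probe_dur,
                           value = probe_seq)
  out
}

# one Gabor wavelet sampled on t (s), centred at 0
gabor_pulse <- function(t, f_c, phi, sigma) {
  sin(2 * pi * f_c * t + phi) * exp(-(t / sigma)^2)
}

#' Parameters of a Gabor pulse train
#'
#' Defaults mimic the pulse-song pulses of *Drosophila melanogaster*
#' courtship: 250 Hz carrier, zero phase, 4.6 ms Gaussian envelope SD, and a
#' 36 ms inter-pulse interval.
#'
#' @param f_c carrier frequency, Hz.
#' @param phi carrier phase, rad.
#' @param sigma Gaussian envelope SD, s.
#' @param ipi inter-pulse interval, s.
#' @param n_pulses number of pulses, or `NULL` to fill the duration.
#' @param intensity peak amplitude (mm/s).
#' @return list of class `"pulse_params"`.
#' @export
pulse_params <- function(f_c = 250, phi = 0, sigma = 0.0046, ipi = 0.036,
                         n_pulses = NULL, intensity = 1) {
  stopifnot(f_c > 0, sigma > 0, ipi > 0, intensity > 0)
  structure(list(f_c = f_c, phi = phi, sigma = sigma, ipi = ipi,
                 n_pulses = n_pulses, intensity = intensity),
            class = "pulse_params")
}

#' Train of Gabor pulses
#'
#' Sum of Gabor wavelets `sin(2 pi f_c x + phi) exp(-(x/sigma)^2)` centred
#' every `ipi` seconds; overlapping pulses are summed linearly. The waveform
#' is scaled so its peak magnitude equals the requested intensity.
#'
#' @param p a [pulse_params()].
#' @param duration total duration, s.
#' @param sample_rate sampling rate, Hz.
#' @return A [stimulus()] with a `probes` table holding pulse centres.
#' @export
pulse_train <- function(p, duration, sample_rate = 10000) {
  stopifnot(inherits(p, "pulse_params"), duration > 0)
  pad <- 4 * p$sigma
  n_fit <- floor((duration - 2 * pad) / p$ipi) + 1
  n_pulses <- if (is.null(p$n_pulses)) n_fit else p$n_pulses
  if (n_pulses < 1 || pad + (n_pulses - 1) * p$ipi + pad > duration)
    stop("pulses do not fit in the requested duration")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  centers <- pad + (seq_len(n_pulses) - 1) * p$ipi
  x <- numeric(n)
  for (cc in centers) {
    idx <- which(abs(t - cc) <= 5 * p$sigma)
    x[idx] <- x[idx] + gabor_pulse(t[idx] - cc, p$f_c, p$phi, p$sigma)
  }
  peak1 <- max(abs(gabor_pulse(seq(-5 * p$sigma, 5 * p$sigma, by = 1 / sample_rate),
                               p$f_c, p$phi, p$sigma)))
  x <- x * p$intensity / if (max(abs(x)) > 0) max(abs(x)) else peak1
  out <- stimulus(x, sample_rate, "velocity_mm_s")
  out$probes <- data.frame(onset_s = centers, value = p$intensity)
  out
}

#' Pure-tone stimulus
#'
#' `intensity * sin(2 pi freq t)`; intensity is the peak amplitude (the
#' convention used for tones and pulses, as opposed to the SD convention for
#' noise).
#'
#' @param freq frequency in Hz (< Nyquist).
#' @param intensity peak amplitude.
#' @param duration duration, s.
#' @param sample_rate sampling rate, Hz.
#' @param units amplitude units.
#' @return A [stimulus()].
#' @export
sinusoid <- function(freq, intensity, duration, sample_rate = 10000,
                     units = "velocity_mm_s") {
  stopifnot(freq < sample_rate / 2, freq > 0, duration > 0)
  t <- (seq_len(round(duration * sample_rate)) - 1) / sample_rate
  stimulus(intensity * sin(2 * pi * freq * t), sample_rate, units)
}

# unit-sum Gaussian smoothing kernel, SD in seconds
gaussian_kernel <- function(sd_s, sample_rate) {
  half <- ceiling(4 * sd_s * sample_rate)
  tt <- (-half:half) / sample_rate
  k <- exp(-0.5 * (tt / sd_s)^2)
  k / sum(k)
}

#' Smoothed step deflection
#'
#' Rectangular displacement step smoothed with a 1 ms-SD Gaussian window
#' (mimicking the low-pass filtering applied to piezo step commands); the
#' plateau value equals the requested amplitude. Negative amplitudes are
#' supported.
#'
#' @param amplitude plateau displacement, um (signed).
#' @param onset,offset step onset and offset times, s (`onset < offset`).
#' @param duration total duration, s; default `offset + 0.05`.
#' @param sample_rate sampling rate, Hz.
#' @param smooth_sd Gaussian smoothing SD, s.
#' @return A displacement [stimulus()].
#' @export
step_deflection <- function(amplitude, onset, offset, duration = offset + 0.05,
                            sample_rate = 10000, smooth_sd = 0.001) {
  stopifnot(onset < offset, duration >= offset)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- ifelse(t >= onset & t < offset, amplitude, 0)
  k <- gaussian_kernel(smooth_sd, sample_rate)
  x <- apply_fir(x, k)
  stimulus(x, sample_rate, "displacement_um")
}

#' Composite mean/variance interaction protocols
#'
#' Displacement stimuli combining static antennal offsets with superimposed
#' 300 Hz sinusoids (`"offset_then_sine"`: probe intensity tuning under mean
#' adaptation) or sustained 300 Hz sinusoids with superimposed probe steps
#' (`"sine_then_step"`: probe step tuning under variance adaptation). One
#' stimulus per adaptation condition is returned; probe events are annotated
#' in each stimulus' `probes` table.
#'
#' @param offsets static offsets, um (adaptation conditions for
#'   `"offset_then_sine"`).
#' @param sine_intensities sinusoid intensities, mm/s (probes for
#'   `"offset_then_sine"`, adaptation conditions for `"sine_then_step"`).
#' @param step_probes probe step sizes, um (signed; `"sine_then_step"`).
#' @param mode `"offset_then_sine"` or `"sine_then_step"`.
#' @param sine_freq sinusoid frequency, Hz.
#' @param probe_dur probe duration, s.
#' @param gap recovery gap between probes, s.
#' @param burn_in adaptation period before the first probe, s.
#' @param sample_rate sampling rate, Hz.
#' @return A list of displacement [stimulus()] objects, one per condition,
#'   each with `condition` attribute and `probes` table.
#' @export
protocol_mean_variance <- function(offsets = c(-0.44, -0.22, 0, 0.22, 0.44),
                                   sine_intensities = c(0.1, 0.22, 0.5, 1.1),
                                   step_probes = c(-0.78, -0.39, -0.1, -0.01,
                                                   0.01, 0.1, 0.39, 0.78),
                                   mode = c("offset_then_sine", "sine_then_step"),
                                   sine_freq = 300, probe_dur = 0.05,
                                   gap = 0.25, burn_in = 0.3,
                                   sample_rate = 10000) {
  mode <- match.arg(mode)
  dt <- 1 / sample_rate
  make_probe_times <- function(n) burn_in + (seq_len(n) - 1) * (probe_dur + gap)
  out <- list()
  if (mode == "offset_then_sine") {
    amps_um <- velocity_to_displacement(sine_intensities, sine_freq)
    for (o in offsets) {
      onsets <- make_probe_times(length(sine_intensities))
      dur <- max(onsets) + probe_dur + gap
      t <- seq(0, dur - dt, by = dt)
      x <- rep(o, length(t))
      for (j in seq_along(onsets)) {
        idx <- which(t >= onsets[j] & t < onsets[j] + probe_dur)
        x[idx] <- x[idx] + amps_um[j] * sin(2 * pi * sine_freq * (t[idx] - onsets[j]))
      }
      s <- stimulus(x, sample_rate, "displacement_um")
      s$probes <- data.frame(onset_s = onsets, value = sine_intensities)
      attr(s, "condition") <- o
      out[[length(out) + 1]] <- s
    }
  } else {
    for (v in sine_intensities) {
      amp_um <- velocity_to_displacement(v, sine_freq)
      onsets <- make_probe_times(length(step_probes))
      dur <- max(onsets) + probe_dur + gap
      t <- seq(0, dur - dt, by = dt)
      x <- amp_um * sin(2 * pi * sine_freq * t)
      for (j in seq_along(onsets)) {
        idx <- which(t >= onsets[j] & t < onsets[j] + probe_dur)
        x[idx] <- x[idx] + step_probes[j]
      }
      k <- gaussian_kernel(0.001, sample_rate)
      sine_part <- amp_um * sin(2 * pi * sine_freq * t)
      x <- sine_part + apply_fir(x - sine_part, k)  # smooth only the steps
      s <- stimulus(x, sample_rate, "displacement_um")
      s$probes <- data.frame(onset_s = onsets, value = step_probes)
      attr(s, "condition") <- v
      out[[length(out) + 1]] <- s
    }
  }
  out
}
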