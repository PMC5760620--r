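#' Surrogate compound-action-potential recording
#'
#' Turns a model trace into a multi-trial raw-recording proxy with the
#' statistical structure the analysis chain assumes: the model output
#' serves as the ground-truth envelope riding on an oscillatory carrier —
#' for tonal stimuli a sinusoid at twice the dominant stimulus frequency
#' (full-wave rectification doubles the carrier frequency in the compound
#' signal), for noise stimuli the band-passed stimulus itself — plus
#' Gaussian trial noise whose variance is proportional to the local
#' envelope mean (variance proportional to mean, as in the recordings this
#' emulates).
#'
#' @param trace a `"model_trace"` from a tonal or noise stimulus.
#' @param n_trials number of trials (default 20, the experimental count).
#' @param noise_gain proportionality constant between local envelope mean
#'   and trial-noise variance.
#' @param seed integer seed.
#' @param carrier `"auto"` (tone detection by spectral concentration),
#'   `"tone_doubled"`, or `"stimulus"`.
#' @return object of class `"surrogate_recording"`: `trials` (n_trials x
#'   samples matrix), `envelope` (ground truth), `stimulus` (input
#'   samples), `sample_rate`, `noise_gain`, `carrier_freq` (NA for noise
#'   carriers), `seed`, and a `zero_envelope` flag.
#' @export
surrogate_cap <- function(trace, n_trials = 20, noise_gain = 0.02, seed = 1,
                          carrier = c("auto", "tone_doubled", "stimulus")) {
  stopifnot(inherits(trace, "model_trace"), n_trials >= 1, noise_gain >= 0)
  carrier <- match.arg(carrier)
  env <- trace$output
  fs <- trace$sample_rate
  n <- length(env)
  zero_env <- all(env == 0)
  spec <- Mod(stats::fft(trace$input))[seq_len(floor(n / 2))]
  spec[1] <- 0
  peak_bin <- which.max(spec)
  tonal <- if (sum(spec^2) == 0) FALSE else {
    sum(spec[max(1, peak_bin - 2):min(length(spec), peak_bin + 2)]^2) /
      sum(spec^2) > 0.5
  }
  if (carrier == "auto") carrier <- if (tonal) "tone_doubled" else "stimulus"
  if (carrier == "tone_doubled") {
    f0 <- (peak_bin - 1) * fs / n
    t <- (seq_len(n) - 1) / fs
    carr <- sin(2 * pi * 2 * f0 * t)
    carrier_freq <- 2 * f0
  } else {
    s <- trace$input
    carr <- if (stats::sd(s) > 0) s / max(abs(s)) else s
    carrier_freq <- NA_real_
  }
  base <- env * carr
  noise_sd <- sqrt(noise_gain * pmax(env, 0))
  trials <- with_seed(seed, {
    t(vapply(seq_len(n_trials),
             function(i) base + stats::rnorm(n) * noise_sd,
             numeric(n)))
  })
  structure(list(trials = trials, envelope = env,
                 stimulus = trace$input, sample_rate = fs,
                 noise_gain = noise_gain, carrier_freq = carrier_freq,
                 seed = seed, zero_envelope = zero_env),
            class = "surrogate_recording")
}

#' @export
print.surrogate_recording <- function(x, ...) {
  cat(sprintf(
    "<surrogate_recording> %d trials x %d samples @ %g Hz%s%s\n",
    nrow(x$trials), ncol(x$trials), x$sample_rate,
    if (!is.na(x$carrier_freq)) sprintf(", carrier %g Hz", x$carrier_freq)
    else ", noise carrier",
    if (x$zero_envelope) " [zero envelope]" else ""))
  invisible(x)
}

#' Ground-truth fixtures for analysis-chain recovery tests
#'
#' Generates noiseless and noisy exponential transients, sigmoid tuning
#' curves, or Fisher-information profiles with known parameters, so each
#' fitting step can be validated against stored ground truth.
#'
#' @param kind `"exponential"`, `"sigmoid"` or `"fisher"`.
#' @param params named list of ground-truth parameters; missing entries are
#'   filled with defaults (`exponential`: r0 = 2, rmax = 3, tau = 0.010 s;
#'   `sigmoid`/`fisher`: r0 = 0, rmax = 1, alpha = 2, beta = 0).
#' @param noise_sd SD of the additive Gaussian noise in the noisy copy.
#'   The sigmoid/fisher default (0.032) is the SD of a 20-trial average
#'   under the surrogate noise model (trial variance = `noise_gain` times
#'   the mean, `noise_gain` = 0.02, at unit response); the exponential
#'   default (0.1) matches the amplitude-trace noise of the transient
#'   fits.
#' @param seed integer seed.
#' @param n number of samples (exponential trace) or curve points.
#' @param sample_rate sampling rate for time-domain fixtures, Hz.
#' @return list with `kind`, `params`, `x` (time or intensity axis),
#'   `clean`, `noisy`, and for `"fisher"` the true `peak`.
#' @export
recovery_fixtures <- function(kind = c("exponential", "sigmoid", "fisher"),
                              params = list(), noise_sd = NULL, seed = 1,
                              n = NULL, sample_rate = 10000) {
  kind <- match.arg(kind)
  if (is.null(noise_sd))
    noise_sd <- if (kind == "exponential") 0.1 else
      sqrt(0.02 * 1 / 20)  # 20-trial average, variance-proportional noise
  if (kind == "exponential") {
    p <- utils::modifyList(list(r0 = 2, rmax = 3, tau = 0.010), params)
    if (is.null(n)) n <- round(0.15 * sample_rate)
    x <- (seq_len(n) - 1) / sample_rate
    clean <- p$r0 + p$rmax * exp(-x / p$tau)
  } else {
    p <- utils::modifyList(list(r0 = 0, rmax = 1, alpha = 2, beta = 0),
                           params)
    if (is.null(n)) n <- 9
    x <- seq(-4, 4, length.out = n)
    clean <- p$r0 + p$rmax / (1 + exp(-p$alpha * (x - p$beta)))
  }
  noisy <- clean + with_seed(seed, stats::rnorm(length(clean), 0, noise_sd))
  out <- list(kind = kind, params = p, x = x, clean = clean, noisy = noisy,
              noise_sd = noise_sd, seed = seed)
  if (kind == "fisher") {
    grid <- seq(min(x), max(x), by = 0.001)
    s <- 1 / (1 + exp(-p$alpha * (grid - p$beta)))
    r <- p$r0 + p$rmax * s
    info <- (p$rmax * p$alpha * s * (1 - s))^2 / r
    out$peak <- grid[which.max(info)]
  }
  out
}
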