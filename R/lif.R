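#' Leaky integrate-and-fire parameters
#'
#' Voltages are simulated relative to rest (rest = 0, threshold +1 mV,
#' reset to rest), with membrane resistance fixed at 1, so the subthreshold
#' dynamics are `tau_V dV/dt = I_in - V - I_adapt`. The adaptation current
#' decays with `tau_adapt` and increments by `delta_A` at every spike
#' (`delta_A = 0` gives a regular, non-adapting LIF).
#'
#' @param tau_V membrane time constant, s.
#' @param V_thres spike threshold above rest, mV.
#' @param V_res reset potential above rest, mV.
#' @param tau_adapt adaptation-current time constant, s.
#' @param delta_A adaptation increment per spike, mV.
#' @param sigma_stim stimulus input scaling (calibrated so that noise at
#'   1 mm/s drives steady firing in the physiological 50--200 Hz range; see
#'   [calibrate_sigma_stim()]).
#' @param sigma_noise SD of the private Gaussian noise current added at
#'   each Euler step.
#' @param dt Euler step, s (1/20 ms).
#' @return list of class `"lif_params"`.
#' @export
lif_params <- function(tau_V = 0.004, V_thres = 1, V_res = 0,
                       tau_adapt = 0.025, delta_A = 0, sigma_stim = 4.6,
                       sigma_noise = 0, dt = 5e-5) {
  stopifnot(tau_V > 0, dt > 0, V_thres > V_res, delta_A >= 0, tau_adapt > 0)
  structure(list(tau_V = tau_V, V_thres = V_thres, V_res = V_res,
                 tau_adapt = tau_adapt, delta_A = delta_A,
                 sigma_stim = sigma_stim, sigma_noise = sigma_noise,
                 dt = dt), class = "lif_params")
}

#' Low-pass filtered white-noise drive for LIF simulations
#'
#' White Gaussian noise low-pass filtered (4th-order Butterworth, default
#' cutoff 1 kHz), rescaled to unit SD and then shaped by an intensity
#' schedule (SD per block) plus an optional mean offset.
#'
#' @param duration duration, s.
#' @param schedule an [intensity_schedule()], or a single intensity.
#' @param mean_offset constant added after scaling (mm/s).
#' @param cutoff low-pass cutoff, Hz.
#' @param seed integer seed.
#' @param sample_rate sampling rate, Hz (default matches the Euler step).
#' @return a [stimulus()].
#' @export
lif_noise <- function(duration, schedule = 1, mean_offset = 0, cutoff = 1000,
                      seed = NULL, sample_rate = 20000) {
  n <- round(duration * sample_rate)
  x <- with_seed(seed, stats::rnorm(n))
  bf <- signal::butter(4, cutoff / (sample_rate / 2), type = "low")
  y <- as.numeric(signal::filter(bf, x))
  y <- y / stats::sd(y)
  if (!inherits(schedule, "intensity_schedule"))
    schedule <- intensity_schedule(0, schedule)
  stim <- apply_intensity_schedule(stimulus(y, sample_rate), schedule)
  stim$samples <- stim$samples + mean_offset
  stim$seed <- seed
  stim
}

# resample a stimulus to the Euler grid by step-hold
stim_on_grid <- function(stim, n_steps, dt) {
  if (inherits(stim, "stimulus")) {
    idx <- pmin(length(stim$samples),
                floor((seq_len(n_steps) - 1) * dt * stim$sample_rate) + 1L)
    stim$samples[idx]
  } else {
    rep_len(as.numeric(stim), n_steps)
  }
}

# Euler integration of m LIF neurons in parallel; I is a steps x m matrix of
# stimulus currents (already scaled); tau_V may be a scalar or length-m
lif_engine <- function(I, p, tau_V = p$tau_V, seed = NULL) {
  n_steps <- nrow(I)
  m <- ncol(I)
  dt <- p$dt
  with_seed(seed, {
    V <- numeric(m)
    A <- numeric(m)
    sp_step <- integer(0)
    sp_col <- integer(0)
    noisy <- p$sigma_noise > 0
    for (k in seq_len(n_steps)) {
      Ik <- I[k, ]
      if (noisy) Ik <- Ik + p$sigma_noise * stats::rnorm(m)
      V <- V + dt * (Ik - V - A) / tau_V
      A <- A - dt * A / p$tau_adapt
      fired <- V >= p$V_thres
      if (any(fired)) {
        w <- which(fired)
        V[w] <- p$V_res
        A[w] <- A[w] + p$delta_A
        sp_step <- c(sp_step, rep.int(k, length(w)))
        sp_col <- c(sp_col, w)
      }
    }
    list(step = sp_step, col = sp_col)
  })
}

#' Simulate a single LIF neuron
#'
#' Euler integration (step 1/20 ms) of the rest-relative LIF with
#' spike-triggered adaptation current. Input current is
#' `sigma_stim * I_stim + sigma_noise * I_noise` with fresh Gaussian noise
#' each step.
#'
#' @param params a [lif_params()].
#' @param I_stim a [stimulus()] or numeric drive (resampled to the Euler
#'   grid by step-hold); interpreted in stimulus units and scaled by
#'   `sigma_stim`.
#' @param duration simulation length, s; defaults to the stimulus duration.
#' @param seed integer seed for the noise current.
#' @return object of class `"spike_data"` (see [spike_data()]).
#' @export
simulate_lif <- function(params, I_stim, duration = NULL, seed = NULL) {
  if (inherits(I_stim, "stimulus")) {
    if (!all(is.finite(I_stim$samples))) stop("non-finite input")
    if (is.null(duration)) duration <- stim_duration(I_stim)
  } else {
    if (!all(is.finite(I_stim))) stop("non-finite input")
    if (is.null(duration)) stop("duration required for bare numeric input")
  }
  n_steps <- round(duration / params$dt)
  I <- matrix(params$sigma_stim * stim_on_grid(I_stim, n_steps, params$dt),
              ncol = 1)
  r <- lif_engine(I, params, seed = seed)
  n_sp <- length(r$step)
  spike_data(data.frame(neuron = rep(1L, n_sp), trial = rep(1L, n_sp),
                        time_s = r$step * params$dt),
             n_neurons = 1L, n_trials = 1L, duration = duration,
             dt = params$dt, seed = seed)
}

#' Spike data container
#'
#' @param events data frame with columns `neuron`, `trial`, `time_s`
#'   (strictly increasing within each train).
#' @param n_neurons,n_trials population and trial counts.
#' @param duration simulation window, s.
#' @param dt Euler step, s.
#' @param seed seed used.
#' @return object of class `"spike_data"`.
#' @export
spike_data <- function(events, n_neurons, n_trials, duration, dt,
                       seed = NULL) {
  stopifnot(all(events$time_s >= 0), all(events$time_s <= duration))
  ord <- order(events$trial, events$neuron, events$time_s)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, n_neurons = n_neurons,
                 n_trials = n_trials, duration = duration, dt = dt,
                 seed = seed), class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d spikes, %d neurons x %d trials, %.3f s\n",
              nrow(x$events), x$n_neurons, x$n_trials, x$duration))
  invisible(x)
}

#' Simulate a LIF population
#'
#' Three stimulus policies reproduce the population scenarios used to test
#' alternative explanations of adaptive population dynamics:
#'
#' * `"independent_realizations"` — every neuron and trial receives a fresh
#'   realization of the noise stimulus (changes in rate, not stimulus fine
#'   structure, drive the population response);
#' * `"shared_plus_private_noise"` — all neurons share one realization and
#'   receive independent private noise current (permits synchrony effects);
#' * `"range_fractionation"` — two subpopulations; each receives the shared
#'   stimulus only while the stimulus intensity is in its preferred block
#'   (low: first listed intensity; high: second), and zero input otherwise.
#'
#' Heterogeneous membrane time constants (drawn uniformly from
#' `tau_V_range`) model response-diversity scenarios.
#'
#' @param n number of neurons.
#' @param params a [lif_params()].
#' @param stim a [stimulus()] (policies 2, 3; must carry a schedule for
#'   range fractionation) or a generator `function(seed)` returning a
#'   stimulus (policy 1).
#' @param policy stimulus policy, see above.
#' @param n_trials number of trials.
#' @param tau_V_range optional `c(min, max)` for per-neuron tau_V, s.
#' @param seed integer seed.
#' @return a `"spike_data"` with an attached `tau_V` attribute.
#' @export
simulate_population <- function(n, params, stim,
                                policy = c("independent_realizations",
                                           "shared_plus_private_noise",
                                           "range_fractionation"),
                                n_trials = 1, tau_V_range = NULL, seed = 1) {
  policy <- match.arg(policy)
  if (n == 0) {
    return(spike_data(data.frame(neuron = integer(0), trial = integer(0),
                                 time_s = numeric(0)),
                      0L, as.integer(n_trials), 0, params$dt, seed))
  }
  tau_V <- if (is.null(tau_V_range)) rep(params$tau_V, n) else
    with_seed(split_seed(seed, 999),
              stats::runif(n, tau_V_range[1], tau_V_range[2]))
  get_stim <- function(s) if (is.function(stim)) stim(s) else stim
  base_stim <- get_stim(split_seed(seed, 0))
  duration <- stim_duration(base_stim)
  n_steps <- round(duration / params$dt)
  events <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    tr_seed <- split_seed(seed, tr)
    if (policy == "independent_realizations") {
      I <- matrix(0, n_steps, n)
      for (j in seq_len(n)) {
        sj <- get_stim(split_seed(tr_seed, j))
        I[, j] <- params$sigma_stim * stim_on_grid(sj, n_steps, params$dt)
      }
    } else {
      drive <- stim_on_grid(base_stim, n_steps, params$dt)
      if (policy == "range_fractionation") {
        if (is.null(base_stim$schedule))
          stop("range fractionation needs a scheduled stimulus")
        env <- schedule_envelope(base_stim$schedule, n_steps,
                                 1 / params$dt)
        levels <- sort(unique(base_stim$schedule$intensity))
        if (length(levels) < 2)
          stop("range fractionation needs at least two intensity levels")
        lo_gate <- as.numeric(env <= levels[1])
        hi_gate <- as.numeric(env >= levels[length(levels)])
        half <- floor(n / 2)
        I <- params$sigma_stim *
          cbind(matrix(drive * lo_gate, n_steps, half),
                matrix(drive * hi_gate, n_steps, n - half))
      } else {
        I <- params$sigma_stim * matrix(drive, n_steps, n)
      }
    }
    r <- lif_engine(I, params, tau_V = tau_V, seed = split_seed(tr_seed, 7))
    events[[tr]] <- data.frame(neuron = r$col,
                               trial = rep(tr, length(r$col)),
                               time_s = r$step * params$dt)
  }
  out <- spike_data(do.call(rbind, events), as.integer(n),
                    as.integer(n_trials), duration, params$dt, seed)
  attr(out, "tau_V") <- tau_V
  out
}

#' Population response summary: PSTH, CAP proxy and synchrony
#'
#' The PSTH is the trial-averaged population spike count per bin (its sum
#' equals the mean number of population spikes per trial). The CAP proxy
#' convolves the PSTH with a fixed biphasic kernel (derivative of a 1 ms
#' Gaussian), mimicking how a compound extracellular potential reflects
#' synchronous firing. The synchrony index is the mean SD of spike times
#' around population events (PSTH bins exceeding mean + 2 SD).
#'
#' @param spikes a `"spike_data"`.
#' @param bin PSTH bin width, s (>= the Euler step).
#' @return list with `time` (bin centers), `psth` (spikes/bin/trial),
#'   `rate_hz`, `cap_proxy`, `synchrony_sd_s` (NA when no events), and
#'   `n_spikes`.
#' @export
population_summary <- function(spikes, bin = 0.001) {
  stopifnot(bin >= spikes$dt)
  n_bins <- max(1L, ceiling(spikes$duration / bin))
  edges <- (0:n_bins) * bin
  centers <- edges[-1] - bin / 2
  if (nrow(spikes$events) == 0) {
    z <- numeric(n_bins)
    return(list(time = centers, psth = z, rate_hz = z, cap_proxy = z,
                synchrony_sd_s = NA_real_, n_spikes = 0L))
  }
  counts <- tabulate(findInterval(spikes$events$time_s, edges,
                                  rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  psth <- counts / spikes$n_trials
  kt <- seq(-0.004, 0.004, by = bin)
  kernel <- -kt / 0.001^2 * exp(-0.5 * (kt / 0.001)^2)
  kernel <- kernel / max(abs(kernel))
  cap <- as.numeric(stats::filter(c(psth, numeric(length(kernel))), kernel,
                                  method = "convolution", sides = 2))
  cap <- cap[seq_len(n_bins)]
  cap[is.na(cap)] <- 0
  thr <- mean(psth) + 2 * stats::sd(psth)
  ev_bins <- which(psth > thr)
  sync <- NA_real_
  if (length(ev_bins) > 0) {
    sds <- vapply(ev_bins, function(b) {
      sel <- spikes$events$time_s >= edges[b] - bin &
        spikes$events$time_s < edges[b + 1] + bin
      if (sum(sel) < 2) return(NA_real_)
      stats::sd(spikes$events$time_s[sel])
    }, numeric(1))
    sync <- mean(sds, na.rm = TRUE)
  }
  list(time = centers, psth = psth, rate_hz = psth / bin / 1,
       cap_proxy = cap, synchrony_sd_s = sync,
       n_spikes = nrow(spikes$events))
}

#' Calibrate the stimulus scaling of a LIF model
#'
#' Adjusts `sigma_stim` so that the steady-state firing rate under noise at
#' the reference intensity falls at `target_rate` (bisection on a
#' monotone rate--gain relation).
#'
#' @param params a [lif_params()].
#' @param target_rate desired steady rate, Hz.
#' @param intensity reference noise intensity (mm/s).
#' @param duration calibration stimulus length, s.
#' @param seed integer seed.
#' @return the calibrated `lif_params`.
#' @export
calibrate_sigma_stim <- function(params, target_rate = 100, intensity = 1,
                                 duration = 1, seed = 1) {
  stim <- lif_noise(duration, intensity, seed = seed)
  rate_at <- function(g) {
    p <- params
    p$sigma_stim <- g
    sd <- simulate_lif(p, stim, seed = split_seed(seed, 2))
    nrow(sd$events) / duration
  }
  lo <- 0.1
  hi <- 100
  for (i in 1:30) {
    mid <- sqrt(lo * hi)
    if (rate_at(mid) < target_rate) lo <- mid else hi <- mid
  }
  params$sigma_stim <- sqrt(lo * hi)
  params
}
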