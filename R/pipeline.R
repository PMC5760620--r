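#' Experiment configuration
#'
#' Validated configuration for the end-to-end experiment runners. The
#' experiment ids mirror the study's figure-level analyses; unknown
#' configuration keys are rejected and a hash of the configuration is
#' stamped into all outputs.
#'
#' @param experiment one of `"fig1_steps"`, `"fig2_background_probe"`,
#'   `"fig3_song"`, `"fig5_interaction"`, `"fig6_model"`, `"motif_search"`,
#'   `"lif_controls"`.
#' @param seed global seed; per-stage seeds are derived with [split_seed()].
#' @param stimulus,model,analysis,lif named lists of stage-parameter
#'   overrides (validated against the known parameter names of each stage).
#' @param output_dir optional output directory for [write_outputs()].
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(experiment, seed = 1, stimulus = list(),
                              model = list(), analysis = list(),
                              lif = list(), output_dir = NULL) {
  experiments <- c("fig1_steps", "fig2_background_probe", "fig3_song",
                   "fig5_interaction", "fig6_model", "motif_search",
                   "lif_controls")
  if (!experiment %in% experiments)
    stop("unknown experiment id: ", experiment)
  check_keys <- function(block, allowed, what) {
    bad <- setdiff(names(block), allowed)
    if (length(bad) > 0)
      stop(sprintf("unknown %s config key(s): %s", what,
                   paste(bad, collapse = ", ")))
    block
  }
  stimulus <- check_keys(stimulus, c("band", "block", "intensities",
                                     "duration", "n_reps", "sample_rate"),
                         "stimulus")
  model <- check_keys(model, c("tau_sub", "tau_div", "sigma_div",
                               "rect_mode"), "model")
  analysis <- check_keys(analysis, c("onset_window", "steady_window"),
                         "analysis")
  lif <- check_keys(lif, c("n", "n_trials", "tau_adapt", "delta_A",
                           "sigma_stim", "sigma_noise"), "lif")
  cfg <- structure(list(experiment = experiment, seed = seed,
                        stimulus = stimulus, model = model,
                        analysis = analysis, lif = lif,
                        output_dir = output_dir),
                   class = "experiment_config")
  attr(cfg, "hash") <- config_hash(unclass(cfg))
  cfg
}

model_params_from <- function(config) {
  do.call(stage_params, config$model)
}

#' Steady-state pulse-train tuning for the inter-pulse interval
#'
#' Runs the canonical model on Gabor pulse trains of varying inter-pulse
#' interval and measures the steady-state per-pulse response (peak output
#' around each pulse center after `steady_after` seconds). Because divisive
#' adaptation accumulates more at short intervals, the response grows with
#' the interval: the model high-pass filters the inter-pulse interval.
#'
#' @param ipis inter-pulse intervals, s.
#' @param intensity pulse peak intensity, mm/s.
#' @param duration train duration, s.
#' @param steady_after only pulses after this time count as steady state, s.
#' @param params a [stage_params()].
#' @return data frame with `ipi_s` and `response`.
#' @export
ipi_response_curve <- function(ipis = c(0.008, 0.016, 0.024, 0.036, 0.048,
                                        0.072),
                               intensity = 4, duration = 2,
                               steady_after = 1.4, params = stage_params()) {
  resp <- vapply(ipis, function(ipi) {
    stim <- pulse_train(pulse_params(ipi = ipi, intensity = intensity),
                        duration)
    tr <- run_motif(network_motif(serial = c("S", "R", "D")), stim, params)
    fs <- stim$sample_rate
    centers <- stim$probes$onset_s
    centers <- centers[centers >= steady_after &
                         centers <= duration - ipi / 2]
    peaks <- vapply(centers, function(cc) {
      i0 <- max(1L, round((cc - ipi / 2) * fs))
      i1 <- min(length(tr$output), round((cc + ipi / 2) * fs))
      max(tr$output[i0:i1])
    }, numeric(1))
    mean(peaks)
  }, numeric(1))
  data.frame(ipi_s = ipis, response = resp)
}

# dominant non-DC frequency of a series
dominant_frequency <- function(x, sample_rate) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  (which.max(spec) - 1) * sample_rate / n
}

run_fig1_steps <- function(config) {
  p <- model_params_from(config)
  block <- config$stimulus$block %||% 0.1
  stim <- protocol_noise_steps(config$stimulus$intensities %||%
                                 c(0.25, 0.5, 1, 2),
                               block = block,
                               seed = split_seed(config$seed, 1))
  tr <- canonical_model(stim, p)
  sched <- stim$schedule
  segs <- data.frame(onset_s = sched$onset_s,
                     end_s = c(sched$onset_s[-1], stim_duration(stim)),
                     x = sched$intensity)
  segs <- segs[-1, ]  # first block has no preceding adaptation state
  tc <- tuning_curve(tr$output, segs,
                     onset_window = config$analysis$onset_window %||% 0.008,
                     steady_window = config$analysis$steady_window %||% 0.010,
                     sample_rate = stim$sample_rate)
  strength <- adaptation_strength(tc$onset, tc$steady)
  taus <- vapply(seq_len(nrow(segs)), function(i) {
    f <- fit_exponential(tr$output, c(segs$onset_s[i], segs$end_s[i]),
                         stim$sample_rate)
    if (f$converged) f$tau else NA_real_
  }, numeric(1))
  list(summary = list(adaptation_strength = strength,
                      tau_median_s = stats::median(taus, na.rm = TRUE),
                      n_transitions = nrow(segs)),
       tables = list(onset_tuning = as.data.frame(tc$onset),
                     steady_tuning = as.data.frame(tc$steady),
                     transient_taus = data.frame(onset_s = segs$onset_s,
                                                 intensity = segs$x,
                                                 tau_s = taus)),
       arrays = list(output = tr$output))
}

run_fig2_background_probe <- function(config) {
  p <- model_params_from(config)
  va <- variance_adaptation_analysis(params = p,
                                     seed = split_seed(config$seed, 2),
                                     n_replicates = 5,
                                     n_reps = config$stimulus$n_reps %||% 40)
  fit_tab <- do.call(rbind, lapply(seq_along(va$mean_fits), function(i) {
    f <- va$mean_fits[[i]]
    data.frame(background = va$backgrounds[i], r0 = f$r0, rmax = f$rmax,
               alpha = f$alpha, beta = f$beta,
               fisher_peak_dev = va$fisher_devs[i])
  }))
  list(summary = list(shift_slope = va$shift_slope,
                      shift_r2 = va$shift_r2,
                      fisher_max_dev = va$fisher_max_dev,
                      min_fit_r2 = va$min_fit_r2),
       tables = list(sigmoid_fits = fit_tab),
       arrays = list())
}

run_fig3_song <- function(config) {
  p <- model_params_from(config)
  fs <- 10000
  tone <- sinusoid(300, 4, 1)
  tr <- canonical_model(tone, p)
  burn <- round(0.3 * fs)
  f_dom <- dominant_frequency(tr$output[-(seq_len(burn))], fs)
  ipi_curve <- ipi_response_curve(params = p)
  intensities <- c(0.06, 0.125, 0.25, 0.5, 1, 2, 4)
  sine_resp <- vapply(intensities, function(a) {
    trr <- canonical_model(sinusoid(300, a, 0.8), p)
    c(onset = mean(trr$output[seq(1, round(0.008 * fs))]),
      steady = mean(trr$output[round(0.79 * fs):round(0.8 * fs)]))
  }, numeric(2))
  list(summary = list(doubling_freq_hz = f_dom,
                      ipi_monotone = as.numeric(all(diff(ipi_curve$response) >= 0))),
       tables = list(ipi_tuning = ipi_curve,
                     sine_tuning = data.frame(intensity = intensities,
                                              onset = sine_resp["onset", ],
                                              steady = sine_resp["steady", ])),
       arrays = list(tone_output = tr$output))
}

run_fig5_interaction <- function(config) {
  p <- model_params_from(config)
  proto <- eval_protocol(params = p, seed = split_seed(config$seed, 5))
  ev <- evaluate_motif(network_motif(serial = c("S", "R", "D")), proto, p)
  s <- adaptation_summary(ev)
  list(summary = list(offset_shift_frac = s$offset_shift_frac,
                      step_slope_monotone = as.numeric(isTRUE(s$step_slope_monotone))),
       tables = list(step_slopes = data.frame(
         background = ev$paradigms$step_noise$conditions,
         slope = s$step_slopes)),
       arrays = list())
}

run_fig6_model <- function(config) {
  p <- model_params_from(config)
  step <- step_deflection(0.44, 0.1, 0.11, 0.3)   # 10 ms step
  sine <- sinusoid(400, 1, 0.3)
  tr_step <- canonical_model(step, p)
  tr_sine <- canonical_model(sine, p)
  proto <- eval_protocol(params = p, seed = split_seed(config$seed, 6))
  ev <- evaluate_motif(network_motif(serial = c("S", "R", "D")), proto, p)
  s <- adaptation_summary(ev)
  curve_tab <- do.call(rbind, lapply(names(ev$paradigms), function(pn) {
    pp <- ev$paradigms[[pn]]
    do.call(rbind, lapply(seq_along(pp$curves), function(i) {
      cbind(paradigm = pn, condition = pp$conditions[i], pp$curves[[i]])
    }))
  }))
  list(summary = c(list(pass = as.numeric(ev$pass)),
                   s[c("shift_slope", "shift_r2", "fisher_max_dev",
                       "offset_shift_frac")]),
       tables = list(tuning_curves = curve_tab),
       arrays = list(step_output = tr_step$output,
                     step_ada_sub = tr_step$stages[[1]]$ada,
                     sine_output = tr_sine$output,
                     sine_ada_sub = tr_sine$stages[[1]]$ada))
}

run_motif_search <- function(config) {
  ser <- enumerate_serial()
  par <- enumerate_parallel()
  battery <- motif_battery(seed = split_seed(config$seed, 3))
  p <- model_params_from(config)
  dd_ser <- dedup_functional(ser, battery, params = p)
  dd_par <- dedup_functional(par, battery, params = p)
  reps <- c(dd_ser$motifs[dd_ser$representatives],
            dd_par$motifs[dd_par$representatives])
  proto <- eval_protocol(params = p, seed = split_seed(config$seed, 4))
  evs <- lapply(reps, evaluate_motif, protocol = proto, params = p)
  sel <- select_matching(evs)
  ev_tab <- do.call(rbind, lapply(seq_along(evs), function(i) {
    ev <- evs[[i]]
    do.call(rbind, lapply(names(ev$paradigms), function(pn) {
      pp <- ev$paradigms[[pn]]
      data.frame(motif = format(ev$motif), paradigm = pn,
                 cv_shift = pp$cv_shift, cv_slope = pp$cv_slope,
                 fit_failed = pp$fit_failed, pass = ev$pass)
    }))
  }))
  list(summary = list(serial_raw = ser$raw_count,
                      serial_structural = ser$structural_count,
                      serial_functional = dd_ser$n_classes,
                      parallel_raw = par$raw_count,
                      parallel_structural = par$structural_count,
                      parallel_functional = dd_par$n_classes,
                      n_selected = length(sel),
                      canonical_selected = as.numeric(any(vapply(
                        evs[sel], function(e) format(e$motif) == "[S>R>D]",
                        logical(1))))),
       tables = list(
         serial_catalogue = data.frame(
           canonical = ser$canonical,
           class = dd_ser$classes,
           representative = seq_along(ser$motifs) %in% dd_ser$representatives),
         parallel_catalogue = data.frame(
           canonical = par$canonical,
           class = dd_par$classes,
           representative = seq_along(par$motifs) %in% dd_par$representatives),
         evaluations = ev_tab,
         selected = data.frame(motif = vapply(evs[sel],
                                              function(e) format(e$motif),
                                              character(1)))),
       arrays = list())
}

run_lif_controls <- function(config) {
  n <- config$lif$n %||% 100
  n_trials <- config$lif$n_trials %||% 20
  seed <- split_seed(config$seed, 9)
  sched <- intensity_schedule(c(0, 0.4, 0.8), c(1, 2, 1))
  stim_fn <- function(s) lif_noise(1.2, sched, seed = s)
  p_reg <- lif_params(delta_A = 0,
                      sigma_stim = config$lif$sigma_stim %||% 4.6)
  p_ada <- lif_params(delta_A = config$lif$delta_A %||% 1,
                      tau_adapt = config$lif$tau_adapt %||% 0.025,
                      sigma_stim = config$lif$sigma_stim %||% 4.6)
  pop_reg <- simulate_population(n, p_reg, stim_fn,
                                 "independent_realizations",
                                 n_trials = n_trials, seed = seed)
  pop_ada <- simulate_population(n, p_ada, stim_fn,
                                 "independent_realizations",
                                 n_trials = n_trials,
                                 seed = split_seed(seed, 1))
  sum_reg <- population_summary(pop_reg, bin = 0.005)
  sum_ada <- population_summary(pop_ada, bin = 0.005)
  transient_contrast <- function(s, t_switch) {
    # rate just after the switch vs adapted rate before the next epoch ends
    sel_on <- s$time > t_switch & s$time <= t_switch + 0.02
    sel_ss <- s$time > t_switch + 0.25 & s$time <= t_switch + 0.38
    mean(s$psth[sel_on]) / mean(s$psth[sel_ss])
  }
  list(summary = list(
    reg_up_contrast = transient_contrast(sum_reg, 0.4),
    ada_up_contrast = transient_contrast(sum_ada, 0.4),
    reg_down_contrast = transient_contrast(sum_reg, 0.8),
    ada_down_contrast = transient_contrast(sum_ada, 0.8),
    reg_rate_hz = sum_reg$n_spikes / n / n_trials / 1.2,
    ada_rate_hz = sum_ada$n_spikes / n / n_trials / 1.2),
    tables = list(psth = data.frame(time = sum_reg$time,
                                    regular = sum_reg$psth,
                                    adaptive = sum_ada$psth)),
    arrays = list())
}

#' Run a configured experiment end to end
#'
#' Executes the named protocol through stimulus synthesis, model or LIF
#' simulation, and the analysis chain, returning a result bundle with a
#' machine-readable scalar summary, result tables, and arrays, fully
#' reproducible from the configuration and its seed.
#'
#' @param config an [experiment_config()].
#' @return list of class `"result_bundle"`: `experiment`, `summary` (named
#'   scalars), `tables` (data frames), `arrays` (numeric vectors),
#'   `config`, `config_hash`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  runner <- switch(config$experiment,
                   fig1_steps = run_fig1_steps,
                   fig2_background_probe = run_fig2_background_probe,
                   fig3_song = run_fig3_song,
                   fig5_interaction = run_fig5_interaction,
                   fig6_model = run_fig6_model,
                   motif_search = run_motif_search,
                   lif_controls = run_lif_controls)
  res <- tryCatch(runner(config), error = function(e) {
    stop(sprintf("experiment '%s' failed: %s", config$experiment,
                 conditionMessage(e)), call. = FALSE)
  })
  structure(c(res, list(experiment = config$experiment, config = config,
                        config_hash = attr(config, "hash"))),
            class = "result_bundle")
}

#' List the available experiments
#' @return character vector of experiment ids.
#' @export
list_experiments <- function() {
  c("fig1_steps", "fig2_background_probe", "fig3_song", "fig5_interaction",
    "fig6_model", "motif_search", "lif_controls")
}

#' Write a result bundle to disk
#'
#' Scalars go to `summary.json` (with the experiment id and configuration
#' hash), tables to one CSV each, arrays to one single-column CSV each.
#'
#' @param bundle a `"result_bundle"`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("csv", "json")`.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(bundle, dir, formats = c("csv", "json")) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- character(0)
  if ("json" %in% formats) {
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(
      list(experiment = bundle$experiment,
           config_hash = bundle$config_hash,
           schema_version = "1",
           summary = bundle$summary),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, f)
  }
  if ("csv" %in% formats) {
    for (nm in names(bundle$tables)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(bundle$tables[[nm]], f, row.names = FALSE)
      paths <- c(paths, f)
    }
    for (nm in names(bundle$arrays)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(data.frame(value = bundle$arrays[[nm]]), f,
                       row.names = FALSE)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
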