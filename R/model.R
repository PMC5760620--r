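#' Stage parameters for the adaptation network
#'
#' Defaults follow the canonical model: subtractive time constant 30 ms,
#' divisive time constant 50 ms, divisive regularizer 1e-4, full-wave
#' rectification.
#'
#' @param tau_sub subtractive-stage time constant, s.
#' @param tau_div divisive-stage time constant, s.
#' @param sigma_div divisive denominator floor (dimensionless, in signal
#'   units). Small values give near-complete divisive adaptation; values
#'   comparable to the adaptation signal weaken it.
#' @param rect_mode `"full"` (absolute value) or `"half"` (negative parts
#'   zeroed).
#' @return list of class `"stage_params"`.
#' @export
stage_params <- function(tau_sub = 0.030, tau_div = 0.050, sigma_div = 1e-4,
                         rect_mode = c("full", "half")) {
  rect_mode <- match.arg(rect_mode)
  stopifnot(tau_sub > 0, tau_div > 0, sigma_div > 0)
  structure(list(tau_sub = tau_sub, tau_div = tau_div, sigma_div = sigma_div,
                 rect_mode = rect_mode), class = "stage_params")
}

#' Leaky integration (first-order low-pass)
#'
#' Exponential-kernel low-pass filter with unit-area kernel, computed with
#' the exact exponential-hold recursion `y[n] = a y[n-1] + (1-a) x[n]`,
#' `a = exp(-dt/tau)`, state initialized at zero. The unit-area
#' normalization makes the steady-state response to a constant input equal
#' that constant, so a subtractive stage built on it nulls DC exactly.
#'
#' @param x numeric series.
#' @param tau time constant, s; must be at least two sample intervals.
#' @param sample_rate sampling rate, Hz.
#' @return filtered series, same length as `x`.
#' @export
leaky_integrate <- function(x, tau, sample_rate = 10000) {
  dt <- 1 / sample_rate
  if (tau < 2 * dt)
    stop(sprintf("tau = %g s is below the resolution limit (2 dt = %g s)",
                 tau, 2 * dt))
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

#' Subtractive adaptation stage (incoherent feedforward loop)
#'
#' The input is low-pass filtered to an adaptation signal which is
#' subtracted from the input: `out = x - leaky_integrate(x, tau)`. Constant
#' inputs are nulled at steady state; fluctuations much faster than `tau`
#' (sound-induced vibrations) pass essentially unchanged.
#'
#' @inheritParams leaky_integrate
#' @return list with `out` and the adaptation signal `ada`.
#' @export
subtract_stage <- function(x, tau, sample_rate = 10000) {
  ada <- leaky_integrate(x, tau, sample_rate)
  list(out = x - ada, ada = ada)
}

#' Divisive adaptation stage (incoherent feedforward loop)
#'
#' The input is low-pass filtered to an adaptation signal which divides the
#' input: `out = x / (c + ada)` with `c = 2e-6 / sigma_div`. The constant
#' `c` keeps the gain finite in the absence of stimulation, and
#' `sigma_div` controls the completeness of adaptation through it:
#' adaptation is near-complete while the adaptation signal dominates the
#' constant (large `sigma_div`, small `c`), and fades out when `sigma_div`
#' is small enough that the constant swamps the adaptation signal. At the
#' default `sigma_div = 1e-4` the constant is 0.02 in stimulus units —
#' at the lower edge of the 0.1--1 mm/s dynamic range of the auditory
#' receptor neurons — so divisive adaptation is essentially complete over
#' the behaviorally relevant intensity range while tuning curves measured
#' against silence remain graded rather than fully self-normalized.
#'
#' For signed inputs the adaptation signal can transiently drive the
#' denominator negative; it is floored at `1e-9` and a `floored` flag is
#' attached when this happens (arbitrary network arrangements can reach
#' this regime; the canonical model, whose divisive stage only sees
#' rectified input, does not).
#'
#' @inheritParams leaky_integrate
#' @param sigma_div completeness parameter (dimensionless); the additive
#'   denominator constant is `2e-6 / sigma_div`.
#' @return list with `out`, `ada`, and logical `floored`.
#' @export
divide_stage <- function(x, tau, sigma_div = 1e-4, sample_rate = 10000) {
  stopifnot(sigma_div > 0)
  ada <- leaky_integrate(x, tau, sample_rate)
  den <- divisive_floor(sigma_div) + ada
  floored <- any(den < 1e-9)
  den[den < 1e-9] <- 1e-9
  list(out = x / den, ada = ada, floored = floored)
}

#' Denominator constant of the divisive stage
#' @param sigma_div completeness parameter.
#' @return the additive constant `2e-6 / sigma_div`.
#' @export
divisive_floor <- function(sigma_div) 2e-6 / sigma_div

#' Rectification
#'
#' Full-wave (`|x|`) or half-wave (negative parts set to zero)
#' rectification. Rectification converts signal variance into signal mean,
#' which is what lets a subsequent divisive loop adapt to sound intensity;
#' full-wave rectification of a tone also doubles its frequency.
#'
#' @param x numeric series.
#' @param mode `"full"` or `"half"`.
#' @return rectified series.
#' @export
rectify <- function(x, mode = c("full", "half")) {
  mode <- match.arg(mode)
  if (mode == "full") abs(x) else pmax(x, 0)
}

#' Execute an adaptation network on a stimulus
#'
#' Runs the nodes of a [network_motif()] over the stimulus samples,
#' recording every intermediate signal. Serial motifs execute their nodes in
#' order; parallel motifs run the input node, feed both branches the same
#' signal, sum the branch outputs sample-wise, and run the output node.
#'
#' @param motif a [network_motif()].
#' @param stim a [stimulus()] (or bare numeric vector at 10 kHz).
#' @param params a [stage_params()].
#' @return A `"model_trace"`: list with `input`, `stages` (per-stage label,
#'   output `out` and, for adaptation stages, adaptation signal `ada`),
#'   final `output`, `sample_rate`, `params`, and a `floored` flag.
#' @export
run_motif <- function(motif, stim, params = stage_params()) {
  if (!inherits(motif, "network_motif")) stop("motif must be a network_motif")
  ok <- motif_validate(motif)
  if (!isTRUE(ok)) stop("malformed motif: ", ok)
  if (inherits(stim, "stimulus")) {
    x <- stim$samples; fs <- stim$sample_rate
  } else {
    x <- as.numeric(stim); fs <- 10000
  }
  floored <- FALSE
  run_nodes <- function(xin, nodes, prefix) {
    stages <- list()
    cur <- xin
    for (nd in nodes) {
      st <- switch(nd,
        S = {
          r <- subtract_stage(cur, params$tau_sub, fs)
          list(label = paste0(prefix, "S"), out = r$out, ada = r$ada)
        },
        D = {
          r <- divide_stage(cur, params$tau_div, params$sigma_div, fs)
          floored <<- floored || r$floored
          list(label = paste0(prefix, "D"), out = r$out, ada = r$ada)
        },
        R = list(label = paste0(prefix, "R"),
                 out = rectify(cur, params$rect_mode), ada = NULL),
        stop("unknown node label: ", nd))
      stages[[length(stages) + 1]] <- st
      cur <- st$out
    }
    list(out = cur, stages = stages)
  }
  stages <- list()
  if (motif$topology == "serial") {
    r <- run_nodes(x, motif$nodes, "")
    stages <- r$stages
    out <- r$out
  } else {
    rin <- run_nodes(x, motif$input, "in:")
    stages <- rin$stages
    b1 <- run_nodes(rin$out, motif$branch1, "b1:")
    b2 <- run_nodes(rin$out, motif$branch2, "b2:")
    stages <- c(stages, b1$stages, b2$stages)
    merged <- b1$out + b2$out
    stages[[length(stages) + 1]] <- list(label = "sum", out = merged, ada = NULL)
    rout <- run_nodes(merged, motif$output, "out:")
    stages <- c(stages, rout$stages)
    out <- rout$out
  }
  structure(list(input = x, stages = stages, output = out, sample_rate = fs,
                 params = params, motif = motif, floored = floored),
            class = "model_trace")
}

#' @export
print.model_trace <- function(x, ...) {
  cat(sprintf("<model_trace> motif %s, %d samples @ %g Hz, %d stages%s\n",
              format(x$motif), length(x$input), x$sample_rate,
              length(x$stages),
              if (x$floored) " [divisive denominator floored]" else ""))
  invisible(x)
}

#' The canonical subtractive -> rectify -> divisive model
#'
#' Runs the serial arrangement S, R, D with default parameters (tau_sub =
#' 30 ms, tau_div = 50 ms, sigma_div = 1e-4, full-wave rectification): the
#' only arrangement of these computations that corrects for the stimulus
#' mean without affecting sound sensitivity while divisively correcting for
#' sound intensity.
#'
#' @param stim a [stimulus()].
#' @param params a [stage_params()].
#' @return A `"model_trace"` (see [run_motif()]).
#' @export
canonical_model <- function(stim, params = stage_params()) {
  run_motif(network_motif(serial = c("S", "R", "D")), stim, params)
}
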