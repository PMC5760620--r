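#' Instantaneous amplitude via the analytic signal
#'
#' Magnitude of the analytic signal (the Hilbert-transform envelope),
#' computed with the standard FFT construction. Unlike RMS-style envelope
#' estimates this imposes no smoothing-window timescale, which is why it is
#' the right pre-processing for sub-millisecond response transients.
#'
#' @param x numeric series (at least a few carrier cycles long).
#' @return non-negative envelope, same length as `x`; if `x` is constant the
#'   absolute value is returned with attribute `constant_input = TRUE`.
#' @export
instantaneous_amplitude <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0) {
    out <- abs(x)
    attr(out, "constant_input") <- TRUE
    return(out)
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Exponential fit to an adaptation transient
#'
#' Least-squares fit of `r(t) = r0 + rmax * exp(-t/tau)` to the
#' falling/rising phase of a response transient. The fit runs from the
#' post-switch extremum of the trace (searched within the first
#' `extremum_search` seconds of the window) to the window end; `t` is
#' measured from the extremum.
#'
#' @param trace numeric response trace (e.g. an amplitude trace).
#' @param window `c(start, end)` in seconds, within the trace.
#' @param sample_rate sampling rate, Hz.
#' @param extremum_search how far after the window start to look for the
#'   transient extremum, s.
#' @return object of class `"exp_fit"`: `r0`, `rmax`, `tau` (s),
#'   `r_squared`, `converged`, `window`, `t_extremum`. Non-convergence or a
#'   flat trace yields `converged = FALSE` rather than an error.
#' @export
fit_exponential <- function(trace, window, sample_rate = 10000,
                            extremum_search = 0.030) {
  n <- length(trace)
  i0 <- max(1L, round(window[1] * sample_rate) + 1L)
  i1 <- min(n, round(window[2] * sample_rate))
  if (i1 <= i0) stop("fit window lies outside the trace")
  y <- trace[i0:i1]
  flagged <- function(reason) {
    structure(list(r0 = NA_real_, rmax = NA_real_, tau = NA_real_,
                   r_squared = NA_real_, converged = FALSE, reason = reason,
                   window = window, t_extremum = NA_real_),
              class = "exp_fit")
  }
  if (stats::sd(y) == 0) return(flagged("flat trace"))
  n_search <- min(length(y), max(2L, round(extremum_search * sample_rate)))
  tail_level <- mean(y[max(1, length(y) - round(0.2 * length(y))):length(y)])
  dev <- abs(y[1:n_search] - tail_level)
  iext <- which.max(dev)
  ys <- y[iext:length(y)]
  tt <- (seq_along(ys) - 1) / sample_rate
  r0_0 <- tail_level
  rmax_0 <- ys[1] - r0_0
  if (abs(rmax_0) < 1e-12 * max(abs(ys), 1)) return(flagged("no transient"))
  tau_0 <- max((tt[length(tt)] - tt[1]) / 5, 2 / sample_rate)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(r0_0, rmax_0, tau_0),
                       fn = function(p) ys - (p[1] + p[2] * exp(-tt / p[3])),
                       lower = c(-Inf, -Inf, 1e-5),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4))
    return(flagged("non-convergence"))
  co <- c(r0 = fit$par[1], rmax = fit$par[2], tau = fit$par[3])
  ss_res <- fit$deviance
  ss_tot <- sum((ys - mean(ys))^2)
  structure(list(r0 = unname(co["r0"]), rmax = unname(co["rmax"]),
                 tau = unname(co["tau"]),
                 r_squared = 1 - ss_res / ss_tot, converged = TRUE,
                 reason = NULL, window = window,
                 t_extremum = window[1] + (iext - 1) / sample_rate),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<exp_fit> tau = %.4g s, r0 = %.4g, rmax = %.4g, r2 = %.3f\n",
                x$tau, x$r0, x$rmax, x$r_squared))
  else cat(sprintf("<exp_fit> not converged (%s)\n", x$reason))
  invisible(x)
}

#' Onset and steady-state tuning curves from a response trace
#'
#' For each probe segment, the onset response is the mean of the trace over
#' the first `onset_window` seconds of the segment and the steady-state
#' response the mean over the last `steady_window` seconds (defaults 8 and
#' 10 ms). Responses are then averaged across segments sharing the same
#' probe value.
#'
#' @param trace numeric response trace (amplitude or model output).
#' @param segments data frame with columns `onset_s`, `end_s` and `x`
#'   (probe value); optionally `group` for averaging signed pairs.
#' @param onset_window,steady_window window lengths, s.
#' @param sample_rate sampling rate, Hz.
#' @param condition optional condition label (e.g. background intensity).
#' @return list with two `"tuning_curve"` data frames (`onset`, `steady`),
#'   each with columns `x`, `response`, `dispersion`, `n`.
#' @export
tuning_curve <- function(trace, segments, onset_window = 0.008,
                         steady_window = 0.010, sample_rate = 10000,
                         condition = NULL) {
  stopifnot(all(c("onset_s", "end_s", "x") %in% names(segments)))
  too_short <- segments$end_s - segments$onset_s < onset_window + steady_window
  if (any(too_short))
    stop(sprintf("segment %d (x = %g) is shorter than onset + steady windows",
                 which(too_short)[1], segments$x[which(too_short)[1]]))
  seg_mean <- function(t0, t1) {
    i0 <- round(t0 * sample_rate) + 1L
    i1 <- min(length(trace), round(t1 * sample_rate))
    mean(trace[i0:i1])
  }
  on_r <- mapply(function(a, b) seg_mean(a, a + onset_window),
                 segments$onset_s, segments$end_s)
  ss_r <- mapply(function(a, b) seg_mean(b - steady_window, b),
                 segments$onset_s, segments$end_s)
  build <- function(resp) {
    sp <- split(resp, segments$x)
    xs <- as.numeric(names(sp))
    o <- order(xs)
    df <- data.frame(x = xs[o],
                     response = vapply(sp, mean, numeric(1))[o],
                     dispersion = vapply(sp, stats::sd, numeric(1))[o],
                     n = vapply(sp, length, integer(1))[o])
    attr(df, "condition") <- condition
    attr(df, "windows") <- c(onset = onset_window, steady = steady_window)
    class(df) <- c("tuning_curve", "data.frame")
    rownames(df) <- NULL
    df
  }
  list(onset = build(on_r), steady = build(ss_r))
}

#' Sigmoid fit to a tuning curve
#'
#' Least-squares fit of `r(x) = r0 + rmax / (1 + exp(-alpha (x - beta)))`,
#' with `x` on a log2 intensity scale for sound probes or a linear um scale
#' for step probes. Initialization is deterministic (`r0` = min, `rmax` =
#' range, `beta` = x at half range, `alpha` from the central rise), with
#' `alpha > 0` enforced for increasing curves; monotone-decreasing curves
#' are fitted with `alpha < 0` and flagged via `decreasing = TRUE`.
#'
#' @param curve a `"tuning_curve"` data frame (or any data frame with `x`
#'   and `response`); at least 5 points.
#' @param nonneg_r0 constrain the baseline `r0` to be non-negative
#'   (appropriate when responses are amplitudes, which cannot be negative;
#'   an unconstrained slightly negative `r0` makes the Fisher-information
#'   profile singular at the fitted zero crossing).
#' @param fix_r0 optional known baseline; when given, `r0` is held at this
#'   value and only `rmax`, `alpha`, `beta` are fitted. Fixing a baseline
#'   the data-generating process is known to lack (model responses vanish
#'   at zero intensity) removes the `r0`--`beta` trade-off that otherwise
#'   destabilizes the fitted position.
#' @return object of class `"sigmoid_fit"`: `r0`, `rmax`, `alpha`, `beta`,
#'   `r_squared`, `slope_max` (= `rmax * alpha / 4`, the curve's maximal
#'   slope in response units), `converged`, `decreasing`.
#' @export
fit_sigmoid <- function(curve, nonneg_r0 = FALSE, fix_r0 = NULL) {
  x <- curve$x
  y <- curve$response
  if (length(x) < 5) stop("sigmoid fit needs at least 5 points")
  flagged <- function(reason) {
    structure(list(r0 = NA_real_, rmax = NA_real_, alpha = NA_real_,
                   beta = NA_real_, r_squared = NA_real_,
                   slope_max = NA_real_, converged = FALSE,
                   decreasing = NA, reason = reason),
              class = "sigmoid_fit")
  }
  if (stats::sd(y) == 0 || !all(is.finite(y))) return(flagged("flat or non-finite curve"))
  decreasing <- stats::cor(x, y) < 0
  yy <- if (decreasing) -y else y
  r0_0 <- min(yy)
  rmax_0 <- max(yy) - min(yy)
  half <- r0_0 + rmax_0 / 2
  beta_0 <- stats::approx(yy, x, xout = half, ties = mean)$y
  if (!is.finite(beta_0)) beta_0 <- stats::median(x)
  iqr <- stats::quantile(x, 0.75) - stats::quantile(x, 0.25)
  mid <- which(yy > r0_0 + 0.25 * rmax_0 & yy < r0_0 + 0.75 * rmax_0)
  alpha_0 <- if (length(mid) >= 2) {
    sl <- stats::coef(stats::lm(yy[mid] ~ x[mid]))[2]
    max(4 * sl / rmax_0, 0.1)
  } else max(4 / max(iqr, diff(range(x)) / 4), 0.1)
  r0_lower <- if (nonneg_r0 && !decreasing) 0 else -Inf
  if (decreasing) fix_r0 <- NULL  # fixed baseline only meaningful rising
  # Levenberg-Marquardt on the residuals directly (nls.lm): robust to the
  # zero-residual degeneracies that model-frame-based fitting can hit on
  # exactly interpolable curves
  sig <- function(p) {
    r0 <- if (is.null(fix_r0)) p[1] else fix_r0
    k <- if (is.null(fix_r0)) 1 else 0
    r0 + p[k + 1] / (1 + exp(-p[k + 2] * (x - p[k + 3])))
  }
  try_fit <- function(a0) {
    par0 <- if (is.null(fix_r0))
      c(max(r0_0, r0_lower), rmax_0, a0, beta_0)
    else c(rmax_0, a0, beta_0)
    lower <- if (is.null(fix_r0)) c(r0_lower, 0, 1e-6, -Inf)
    else c(0, 1e-6, -Inf)
    out <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = function(p) yy - sig(p),
                         lower = lower,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:4)) return(NULL)
    out
  }
  fit <- NULL
  best <- Inf
  for (mult in c(1, 3, 0.3, 10)) {  # deterministic start ladder
    cand <- try_fit(alpha_0 * mult)
    if (!is.null(cand) && cand$deviance < best - 1e-12) {
      fit <- cand
      best <- cand$deviance
    }
  }
  if (is.null(fit)) return(flagged("non-convergence"))
  pp <- fit$par
  co <- if (is.null(fix_r0)) {
    list(r0 = pp[1], rmax = pp[2], alpha = pp[3], beta = pp[4])
  } else {
    list(r0 = fix_r0, rmax = pp[1], alpha = pp[2], beta = pp[3])
  }
  ss_res <- fit$deviance
  ss_tot <- sum((yy - mean(yy))^2)
  # map back to the original orientation: fitting -y with (r0, rmax, alpha)
  # equals fitting y with (-r0 - rmax, rmax, -alpha), keeping rmax >= 0
  if (decreasing) {
    r0_out <- -co$r0 - co$rmax
    alpha_out <- -co$alpha
  } else {
    r0_out <- co$r0
    alpha_out <- co$alpha
  }
  structure(list(r0 = r0_out, rmax = co$rmax,
                 alpha = alpha_out, beta = co$beta,
                 r_squared = 1 - ss_res / ss_tot,
                 slope_max = co$rmax * alpha_out / 4,
                 converged = TRUE, decreasing = decreasing, reason = NULL),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<sigmoid_fit> r0 = %.4g, rmax = %.4g, alpha = %.4g, beta = %.4g, r2 = %.4f\n",
      x$r0, x$rmax, x$alpha, x$beta, x$r_squared))
  else cat(sprintf("<sigmoid_fit> not converged (%s)\n", x$reason))
  invisible(x)
}

#' Evaluate a fitted sigmoid
#' @param fit a converged `"sigmoid_fit"`.
#' @param x evaluation points.
#' @return predicted responses.
#' @export
predict_sigmoid <- function(fit, x) {
  stopifnot(fit$converged)
  fit$r0 + fit$rmax / (1 + exp(-fit$alpha * (x - fit$beta)))
}

#' Adaptation strength from onset and steady-state tuning curves
#'
#' Compares the mean finite-difference slope of the onset curve (`s_on`)
#' with that of the steady-state curve (`s_ss`) and returns
#' `1 - s_ss / s_on`: 0 for no adaptation (identical slopes), approaching 1
#' for complete adaptation (flat steady-state curve), and possibly outside
#' `[0, 1]` for noisy curves.
#'
#' @param onset,steady `"tuning_curve"` data frames sharing the same `x`.
#' @return scalar adaptation strength; `NA` with attribute
#'   `flag = "zero onset slope"` if the onset curve is flat.
#' @export
adaptation_strength <- function(onset, steady) {
  stopifnot(isTRUE(all.equal(onset$x, steady$x)))
  s_on <- mean(diff(onset$response) / diff(onset$x))
  s_ss <- mean(diff(steady$response) / diff(steady$x))
  if (s_on == 0) {
    out <- NA_real_
    attr(out, "flag") <- "zero onset slope"
    return(out)
  }
  1 - s_ss / s_on
}

#' Fisher information profile of a fitted tuning curve
#'
#' With response variance proportional to the mean, the Fisher information
#' carried by a tuning curve is proportional to `(dr/dx)^2 / r(x)`. It is
#' evaluated from the analytic derivative of the sigmoid fit, normalized to
#' a maximum of 1; its peak marks the intensity region of highest
#' discriminability.
#'
#' @param fit a converged `"sigmoid_fit"`.
#' @param x_grid evaluation grid (same axis as the fit).
#' @return object of class `"fisher_curve"`: data frame `x`, `info`
#'   (normalized), plus attributes `peak` (x of the maximum) and `clipped`
#'   (TRUE if grid points with non-positive predicted response were
#'   dropped).
#' @export
fisher_information <- function(fit, x_grid) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) stop("fit did not converge")
  s <- 1 / (1 + exp(-fit$alpha * (x_grid - fit$beta)))
  r <- fit$r0 + fit$rmax * s
  dr <- fit$rmax * fit$alpha * s * (1 - s)
  keep <- r > 0
  clipped <- any(!keep)
  x_grid <- x_grid[keep]
  info <- dr[keep]^2 / r[keep]
  if (length(info) == 0) stop("predicted response non-positive on the whole grid")
  info <- info / max(info)
  out <- data.frame(x = x_grid, info = info)
  attr(out, "peak") <- x_grid[which.max(info)]
  attr(out, "clipped") <- clipped
  class(out) <- c("fisher_curve", "data.frame")
  out
}

#' Regression of tuning-curve shift on log2 background intensity
#'
#' A slope of 1 means the tuning curves shift one octave per octave of
#' background — complete divisive adaptation ("the diagonal"); 0 means no
#' adaptation.
#'
#' @param fits list of converged `"sigmoid_fit"`s, one per background.
#' @param backgrounds background intensities (linear units, e.g. mm/s).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
shift_regression <- function(fits, backgrounds) {
  stopifnot(length(fits) == length(backgrounds))
  if (length(fits) < 3) stop("need at least 3 backgrounds")
  lb <- log2(backgrounds)
  if (stats::sd(lb) == 0) stop("degenerate backgrounds")
  beta <- vapply(fits, function(f) f$beta, numeric(1))
  m <- stats::lm(beta ~ lb)
  r2 <- 1 - sum(stats::residuals(m)^2) / sum((beta - mean(beta))^2)
  list(slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]),
       r_squared = r2)
}
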