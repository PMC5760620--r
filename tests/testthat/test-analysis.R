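test_that("the analytic-signal amplitude recovers envelopes without a
           smoothing timescale", {
  fs <- 10000
  t <- (0:9999) / fs
  x <- 1.7 * sin(2 * pi * 300 * t)
  amp <- instantaneous_amplitude(x)
  interior <- 500:9500
  expect_true(all(abs(amp[interior] - 1.7) < 0.017))

  expect_equal(instantaneous_amplitude(numeric(100)), abs(numeric(100)),
               ignore_attr = TRUE)

  # amplitude-modulated tone: recovered envelope tracks the modulation
  env <- 1 + 0.5 * sin(2 * pi * 10 * t)
  am <- env * sin(2 * pi * 300 * t)
  rec <- instantaneous_amplitude(am)
  expect_gt(stats::cor(rec[interior], env[interior]), 0.99)

  const <- instantaneous_amplitude(rep(3, 100))
  expect_true(isTRUE(attr(const, "constant_input")))
  expect_equal(as.numeric(const), rep(3, 100))

  # scale covariance
  expect_equal(instantaneous_amplitude(2.5 * x), 2.5 * amp,
               tolerance = 1e-10)
})

test_that("exponential transient fits recover their parameters", {
  fs <- 10000
  fx <- recovery_fixtures("exponential", list(r0 = 2, rmax = 3, tau = 0.010))
  f <- fit_exponential(fx$clean, c(0, 0.15), fs)
  expect_true(f$converged)
  expect_equal(f$tau, 0.010, tolerance = 0.01 * 0.010)

  # noisy recovery within 20% across fixtures (simulation oracle)
  errs <- vapply(1:20, function(s) {
    fx <- recovery_fixtures("exponential", noise_sd = 0.1, seed = s)
    f <- fit_exponential(fx$noisy, c(0, 0.15), fs)
    abs(f$tau - fx$params$tau) / fx$params$tau
  }, numeric(1))
  expect_lt(stats::median(errs), 0.2)
  expect_gt(mean(errs < 0.2), 0.8)

  flat <- fit_exponential(rep(1, 1000), c(0, 0.05), fs)
  expect_false(flat$converged)
})

test_that("onset and steady tuning curves honor their windows", {
  fs <- 10000
  trace <- rep(3, 10000)
  segs <- data.frame(onset_s = c(0.1, 0.4, 0.7),
                     end_s = c(0.2, 0.5, 0.8), x = c(1, 2, 4))
  tc <- tuning_curve(trace, segs, sample_rate = fs)
  expect_equal(tc$onset$response, rep(3, 3))
  expect_equal(tc$steady$response, rep(3, 3))
  expect_equal(attr(tc$onset, "windows"),
               c(onset = 0.008, steady = 0.010))

  segs_bad <- data.frame(onset_s = 0.1, end_s = 0.11, x = 1)
  expect_error(tuning_curve(trace, segs_bad, sample_rate = fs), "segment 1")
})

test_that("the model's step-protocol tuning shows graded onsets and a
           near-flat steady state", {
  stim <- protocol_noise_steps(seed = 4)
  tr <- canonical_model(stim)
  sched <- stim$schedule
  segs <- data.frame(onset_s = sched$onset_s,
                     end_s = c(sched$onset_s[-1], stim_duration(stim)),
                     x = sched$intensity)[-1, ]
  tc <- tuning_curve(tr$output, segs, sample_rate = stim$sample_rate)
  s_on <- mean(diff(tc$onset$response) / diff(tc$onset$x))
  s_ss <- mean(diff(tc$steady$response) / diff(tc$steady$x))
  expect_gt(s_on, 3 * s_ss)  # onset strongly graded, steady much flatter
  strength <- adaptation_strength(tc$onset, tc$steady)
  expect_gt(strength, 0.5)
})

test_that("sigmoid fits recover parameters and flag edge cases", {
  x <- seq(-4, 4, length.out = 9)
  y <- 0 + 1 / (1 + exp(-2 * (x - 0)))
  f <- fit_sigmoid(data.frame(x = x, response = y))
  expect_true(f$converged)
  expect_equal(f$r0, 0, tolerance = 1e-4)
  expect_equal(f$rmax, 1, tolerance = 1e-4)
  expect_equal(f$alpha, 2, tolerance = 1e-4)
  expect_equal(f$beta, 0, tolerance = 1e-4)
  expect_equal(f$r_squared, 1, tolerance = 1e-6)

  # monotone-decreasing curve fitted with negative alpha and flagged
  fd <- fit_sigmoid(data.frame(x = x, response = rev(y)))
  expect_true(fd$converged)
  expect_true(fd$decreasing)
  expect_lt(fd$alpha, 0)
  expect_gte(fd$rmax, 0)

  expect_error(fit_sigmoid(data.frame(x = 1:3, response = 1:3)),
               "at least 5")
})

test_that("adaptation strength has the documented limits", {
  x <- 1:6
  onset <- data.frame(x = x, response = 2 * x)
  steady_same <- onset
  steady_flat <- data.frame(x = x, response = rep(1, 6))
  expect_equal(adaptation_strength(onset, steady_same), 0)
  expect_equal(adaptation_strength(onset, steady_flat), 1)

  flat_on <- data.frame(x = x, response = rep(1, 6))
  s <- adaptation_strength(flat_on, steady_flat)
  expect_true(is.na(s))
  expect_equal(attr(s, "flag"), "zero onset slope")
})

test_that("Fisher information is translation-covariant, normalized, and
           matches a brute-force oracle", {
  x <- seq(-4, 4, length.out = 9)
  y <- 1 / (1 + exp(-1.5 * (x - 0.5)))
  f <- fit_sigmoid(data.frame(x = x, response = y))
  grid <- seq(-6, 6, by = 0.001)
  fc <- fisher_information(f, grid)
  expect_equal(max(fc$info), 1)

  # brute-force oracle: maximize (dr/dx)^2 / r numerically from predictions
  r <- predict_sigmoid(f, grid)
  dr <- c(NA, diff(r) / diff(grid))
  oracle_peak <- grid[which.max((dr^2 / r)[-1]) + 1]
  expect_lt(abs(attr(fc, "peak") - oracle_peak), 0.005)

  f2 <- f
  f2$beta <- f$beta + 1
  fc2 <- fisher_information(f2, grid)
  expect_lt(abs(attr(fc2, "peak") - attr(fc, "peak") - 1), 0.002)

  # negative-baseline fits clip the grid and flag it
  f3 <- f
  f3$r0 <- -0.2
  fc3 <- fisher_information(f3, grid)
  expect_true(attr(fc3, "clipped"))
})

test_that("shift regression recovers the diagonal and degenerate slopes", {
  bgs <- c(0.25, 0.5, 1, 2, 4)
  mk_fit <- function(beta) {
    f <- fit_sigmoid(data.frame(x = seq(-4, 4, length.out = 9),
                                response = 1 / (1 + exp(-(seq(-4, 4,
                                  length.out = 9) - 0)))))
    f$beta <- beta
    f
  }
  fits <- lapply(log2(bgs), mk_fit)
  reg <- shift_regression(fits, bgs)
  expect_equal(reg$slope, 1, tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)

  fits0 <- lapply(rep(0.5, 5), mk_fit)
  expect_equal(shift_regression(fits0, bgs)$slope, 0, tolerance = 1e-10)

  expect_error(shift_regression(fits[1:2], bgs[1:2]), "at least 3")
})
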