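test_that("band-limited noise has unit SD, is seed-reproducible, and keeps
           its power inside the pass band", {
  s1 <- bandlimited_noise(1, c(80, 1000), seed = 7)
  s2 <- bandlimited_noise(1, c(80, 1000), seed = 7)
  expect_identical(s1$samples, s2$samples)
  expect_equal(stats::sd(s1$samples), 1, tolerance = 0.001)

  s3 <- bandlimited_noise(1, c(80, 1000), seed = 8)
  expect_false(identical(s1$samples, s3$samples))

  # periodogram oracle on a long realization
  s <- bandlimited_noise(10, c(80, 1000), seed = 1)
  n <- length(s$samples)
  ps <- Mod(stats::fft(s$samples))^2
  freq <- (seq_len(n) - 1) * s$sample_rate / n
  freq <- pmin(freq, s$sample_rate - freq)  # fold to 0..Nyquist
  out_frac <- sum(ps[freq < 80 | freq > 1000]) / sum(ps)
  expect_lt(out_frac, 0.02)
})

test_that("pass bands outside Nyquist are rejected with the limit named", {
  expect_error(bandlimited_noise(0.1, c(80, 6000)), "Nyquist")
})

test_that("intensity schedules scale segments to target SD with 1 ms ramps", {
  carrier <- bandlimited_noise(1, seed = 2)
  sched <- intensity_schedule(0, 2)
  scaled <- apply_intensity_schedule(carrier, sched)
  expect_equal(stats::sd(scaled$samples), 2, tolerance = 0.05)

  # ramp midpoint on a flat unit carrier interpolates the scale linearly
  ones <- stimulus(rep(1, 4000))
  sw <- apply_intensity_schedule(ones, intensity_schedule(c(0, 0.2), c(1, 2)))
  expect_lt(abs(sw$samples[2006] - 1.5), 0.06)
  expect_equal(sw$samples[1999], 1)
  expect_equal(sw$samples[2011], 2)

  # per-block SD within 10% of target across an octave ladder
  carrier <- bandlimited_noise(0.4, seed = 3)
  sched <- intensity_schedule(c(0, 0.1, 0.2, 0.3), c(0.25, 0.5, 1, 2))
  st <- apply_intensity_schedule(carrier, sched)
  for (k in 1:4) {
    idx <- ((k - 1) * 1000 + 20):(k * 1000)
    expect_lt(abs(stats::sd(st$samples[idx]) / sched$intensity[k] - 1), 0.1)
  }

  expect_error(
    apply_intensity_schedule(carrier,
                             intensity_schedule(c(0, 1), c(1, 2))),
    "past the end")
})

test_that("noise-step protocol contains every ordered intensity transition", {
  st <- protocol_noise_steps(c(0.25, 0.5, 1, 2), block = 0.1, seed = 1)
  v <- st$schedule$intensity
  trans <- unique(paste(v[-length(v)], v[-1]))
  expect_equal(length(trans), 12)  # 4 * 3 ordered pairs
  expect_true(all(abs(diff(st$schedule$onset_s) - 0.1) < 1e-9))

  st2 <- protocol_noise_steps(c(1, 2), block = 0.1, seed = 1)
  expect_true(all(abs(diff(st2$schedule$intensity)) == 1))
})

test_that("background-probe protocol timing and probe cycling are correct", {
  st <- protocol_background_probe(1, probes = 2, seed = 1, n_cycles = 5)
  seg <- st$schedule
  ends <- c(seg$onset_s[-1], stim_duration(st))
  probe_time <- sum((ends - seg$onset_s)[seg$intensity == 2])
  expect_equal(probe_time / stim_duration(st), 20 / 120, tolerance = 1e-6)

  st3 <- protocol_background_probe(1, probes = 2^(-3:4), n_cycles = 16,
                                   seed = 1)
  expect_true(all(table(st3$probes$value) == 2))

  expect_error(protocol_background_probe(1, probes = numeric(0)), "empty")
})

test_that("Gabor pulse trains have the right symmetry, spacing, and peak", {
  p <- pulse_params(intensity = 2, n_pulses = 1)
  st <- pulse_train(p, 0.1)
  expect_equal(max(abs(st$samples)), 2, tolerance = 1e-6)
  # odd symmetry at phi = 0: zero crossing at the pulse center
  ic <- round(st$probes$onset_s[1] * st$sample_rate) + 1
  expect_lt(abs(st$samples[ic]), 1e-3 * max(abs(st$samples)))

  train <- pulse_train(pulse_params(), 0.5)
  env <- instantaneous_amplitude(train$samples)
  peaks <- vapply(train$probes$onset_s, function(cc) {
    i <- round(cc * train$sample_rate)
    which.max(env[(i - 100):(i + 100)]) + i - 101
  }, numeric(1))
  expect_true(all(abs(diff(peaks) - 360) <= 1))  # 36 ms at 10 kHz
})

test_that("sinusoids follow the peak-amplitude intensity convention", {
  st <- sinusoid(100, 1.5, 0.5)
  i_quarter <- round(st$sample_rate / (4 * 100)) + 1
  expect_equal(st$samples[i_quarter], 1.5, tolerance = 1e-6)
  expect_equal(mean(st$samples), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(st$samples^2)), 1.5 / sqrt(2), tolerance = 1e-3)
})

test_that("velocity and displacement amplitudes obey v = 2 pi f d", {
  for (f in c(100, 300, 900)) {
    d <- velocity_to_displacement(1, f)
    expect_equal(d * 2 * pi * f / 1000, 1, tolerance = 1e-12)
    expect_equal(displacement_to_velocity(d, f), 1, tolerance = 1e-12)
  }
})

test_that("step deflections are smoothed but keep their plateau", {
  st <- step_deflection(-0.44, 0.05, 0.2)
  plateau <- st$samples[round(0.12 * st$sample_rate)]
  expect_equal(plateau, -0.44, tolerance = 1e-6)
  # smoothed rising edge is monotone
  edge <- st$samples[round(0.044 * st$sample_rate):round(0.056 * st$sample_rate)]
  expect_true(all(diff(edge) <= 1e-12))
})

test_that("mean/variance composite protocols superimpose their components", {
  stims <- protocol_mean_variance(offsets = c(0, 0.44),
                                  sine_intensities = c(0.5),
                                  mode = "offset_then_sine")
  s0 <- stims[[1]]  # zero offset: pure sinusoid during the probe
  on <- s0$probes$onset_s[1]
  idx <- round(on * s0$sample_rate) + 10:100
  amp <- velocity_to_displacement(0.5, 300)
  t <- (idx - 1) / s0$sample_rate - on
  expect_equal(s0$samples[idx], amp * sin(2 * pi * 300 * t),
               tolerance = 1e-8)
  # nonzero offset: same probe plus the offset, sample-wise
  s1 <- stims[[2]]
  expect_equal(s1$samples[idx] - 0.44, s0$samples[idx], tolerance = 1e-6)

  expect_error(protocol_mean_variance(mode = "nope"))
})
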