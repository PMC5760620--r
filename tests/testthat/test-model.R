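test_that("leaky integration has unit DC gain and first-order dynamics", {
  fs <- 10000
  y <- leaky_integrate(rep(1, 5000), 0.03, fs)
  expect_equal(tail(y, 1), 1, tolerance = 1e-3)

  # step response reaches 1 - 1/e after one time constant
  expect_equal(y[round(0.03 * fs)], 1 - exp(-1), tolerance = 0.01)

  # closed-form attenuation of a fast sinusoid: |H| = 1/sqrt(1 + (2 pi f tau)^2)
  x <- sin(2 * pi * 400 * (0:9999) / fs)
  y <- leaky_integrate(x, 0.03, fs)
  expect_lt(max(abs(tail(y, 5000))), 0.02)
  expect_equal(max(abs(tail(y, 5000))),
               1 / sqrt(1 + (2 * pi * 400 * 0.03)^2), tolerance = 0.1)

  expect_error(leaky_integrate(1:10, 1e-5, fs), "resolution")
})

test_that("the subtractive stage nulls DC, passes sound, and is
           scale-covariant", {
  fs <- 10000
  r <- subtract_stage(rep(2, 5000), 0.03, fs)
  expect_equal(tail(r$out, 1), 0, tolerance = 1e-3)
  expect_equal(tail(r$ada, 1), 2, tolerance = 1e-3)

  x <- sin(2 * pi * 400 * (0:9999) / fs)
  r <- subtract_stage(x, 0.03, fs)
  expect_gt(max(tail(r$out, 5000)), 0.98)

  # step input leaves a transient decaying with tau
  xs <- c(rep(0, 100), rep(1, 5000))
  r <- subtract_stage(xs, 0.03, fs)
  expect_equal(r$out[100 + round(0.03 * fs)], exp(-1), tolerance = 0.01)

  for (a in c(0.5, 3)) {
    r1 <- subtract_stage(a * x, 0.03, fs)
    r0 <- subtract_stage(x, 0.03, fs)
    expect_equal(r1$out, a * r0$out, tolerance = 1e-12)
  }
})

test_that("the divisive stage has the documented fixed point and
           sigma_div controls adaptation completeness", {
  fs <- 10000
  r <- divide_stage(rep(0, 1000), 0.05, 1e-4, fs)
  expect_true(all(r$out == 0))

  for (sg in c(1e-4, 1e-2)) {
    r <- divide_stage(rep(1, 20000), 0.05, sg, fs)
    expect_equal(tail(r$out, 1), 1 / (divisive_floor(sg) + 1),
                 tolerance = 1e-3)
  }
  # adaptation weakens as sigma_div shrinks (the denominator constant grows)
  out_small <- tail(divide_stage(rep(1, 20000), 0.05, 1e-8, fs)$out, 1)
  out_default <- tail(divide_stage(rep(1, 20000), 0.05, 1e-4, fs)$out, 1)
  expect_lt(out_small, 0.02)        # swamped by the constant: near-linear
  expect_gt(out_default, 0.9)       # constant negligible: near-complete
})

test_that("rectification modes behave and full-wave doubles tone frequency", {
  expect_equal(rectify(c(-1, 2), "full"), c(1, 2))
  expect_equal(rectify(c(-1, 2), "half"), c(0, 2))

  x <- sinusoid(300, 1, 1)$samples
  y <- rectify(x, "full")
  spec <- Mod(stats::fft(y - mean(y)))[1:5000]
  f_dom <- (which.max(spec) - 1) / 1
  expect_equal(f_dom, 600)
})

test_that("run_motif composes stages faithfully", {
  stim <- stimulus(c(rep(0, 100), rep(1, 2000)))
  p <- stage_params()

  tr <- run_motif(network_motif(serial = "S"), stim, p)
  ref <- subtract_stage(stim$samples, p$tau_sub, stim$sample_rate)
  expect_equal(tr$output, ref$out)
  expect_equal(tr$stages[[1]]$ada, ref$ada)

  tr_r <- run_motif(network_motif(serial = "R"), stim, p)
  tr_rr <- run_motif(network_motif(serial = c("R", "R")), stim, p)
  expect_equal(tr_r$output, tr_rr$output)

  expect_error(network_motif(serial = c("S", "S", "S")), "grammar")
  expect_error(network_motif(serial = "Q"), "grammar")

  # parallel branches are summed sample-wise
  m <- network_motif(input = "0", branch1 = "S", branch2 = "D", output = "0")
  trp <- run_motif(m, stim, p)
  b1 <- subtract_stage(stim$samples, p$tau_sub, stim$sample_rate)$out
  b2 <- divide_stage(stim$samples, p$tau_div, p$sigma_div,
                     stim$sample_rate)$out
  expect_equal(trp$output, b1 + b2)
})

test_that("the canonical model output is non-negative with full traces", {
  tr <- canonical_model(sinusoid(300, 2, 0.5))
  expect_true(all(tr$output >= 0))
  expect_equal(vapply(tr$stages, `[[`, "", "label"), c("S", "R", "D"))
  expect_false(is.null(tr$stages[[1]]$ada))
  expect_true(is.null(tr$stages[[2]]$ada))
  expect_false(is.null(tr$stages[[3]]$ada))
})

test_that("independence of mean and variance adaptation holds for both
           time-constant orderings", {
  for (pars in list(stage_params(tau_sub = 0.015, tau_div = 0.060),
                    stage_params(tau_sub = 0.060, tau_div = 0.015))) {
    proto <- eval_protocol(params = pars, seed = 1,
                           paradigms = c("intensity_offset", "step_noise"))
    ev <- evaluate_motif(network_motif(serial = c("S", "R", "D")), proto,
                         pars)
    s <- adaptation_summary(ev)
    expect_lt(s$offset_shift_frac, 0.05)
    expect_true(s$step_slope_monotone)
  }
})
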