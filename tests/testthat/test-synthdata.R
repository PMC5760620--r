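test_that("surrogate recordings double tonal carrier frequency and carry a
           mean-proportional trial variance", {
  tr <- canonical_model(sinusoid(300, 2, 0.6))
  sur <- surrogate_cap(tr, n_trials = 5, noise_gain = 0, seed = 1)
  expect_equal(sur$carrier_freq, 600)
  expect_true(all(sur$trials[1, ] == sur$trials[5, ]))  # no noise: identical
  spec <- Mod(stats::fft(sur$trials[1, ] - mean(sur$trials[1, ])))
  f_dom <- (which.max(spec[1:3000]) - 1) / 0.6
  expect_equal(f_dom, 600)

  # empirical variance-vs-mean regression through the origin
  sur2 <- surrogate_cap(tr, n_trials = 200, noise_gain = 0.05, seed = 2)
  v <- apply(sur2$trials, 2, stats::var)
  m <- sur2$envelope
  keep <- m > 0.01 * max(m)
  fit <- stats::lm(v[keep] ~ 0 + m[keep])
  expect_equal(unname(stats::coef(fit)), 0.05, tolerance = 0.1 * 0.05)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("zero-envelope traces yield flagged pure-noise surrogates", {
  tr <- canonical_model(stimulus(rep(0, 2000)))
  sur <- surrogate_cap(tr, n_trials = 3, seed = 1)
  expect_true(sur$zero_envelope)
  expect_true(all(sur$trials == 0))  # noise variance scales with envelope
})

test_that("noise-stimulus surrogates use the band-matched stimulus carrier", {
  tr <- canonical_model(bandlimited_noise(0.5, seed = 5))
  sur <- surrogate_cap(tr, n_trials = 2, seed = 1)
  expect_true(is.na(sur$carrier_freq))
})

test_that("recovery fixtures are exact noiseless and 10%-recoverable noisy", {
  fx <- recovery_fixtures("sigmoid", list(alpha = 2, beta = 1))
  f <- fit_sigmoid(data.frame(x = fx$x, response = fx$clean))
  expect_equal(f$alpha, 2, tolerance = 1e-5)
  expect_equal(f$beta, 1, tolerance = 1e-5)

  # Monte-Carlo recovery at trial-averaged noise levels
  errs <- t(vapply(1:50, function(s) {
    fx <- recovery_fixtures("sigmoid", list(alpha = 2, beta = 1),
                            seed = s)
    f <- fit_sigmoid(data.frame(x = fx$x, response = fx$noisy), nonneg_r0 = TRUE)
    c(a = abs(f$alpha - 2) / 2, b = abs(f$beta - 1) / 1)
  }, numeric(2)))
  expect_lt(stats::median(errs[, "a"]), 0.1)
  expect_lt(stats::median(errs[, "b"]), 0.1)

  # fisher fixtures store the analytic peak
  fxf <- recovery_fixtures("fisher", list(alpha = 2, beta = 0.5))
  expect_equal(fxf$peak, 0.5 - log(2) / 2, tolerance = 0.01)
})

test_that("fixture serialization round-trips losslessly", {
  fx <- recovery_fixtures("exponential", seed = 3, noise_sd = 0.05)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  utils::write.csv(data.frame(x = fx$x, clean = fx$clean, noisy = fx$noisy),
                   csv, row.names = FALSE)
  jsonlite::write_json(fx$params, json, auto_unbox = TRUE, digits = NA)
  back <- utils::read.csv(csv)
  expect_equal(back$noisy, fx$noisy)
  expect_equal(jsonlite::read_json(json, simplifyVector = TRUE),
               fx$params)
})

test_that("pipeline estimates converge to stored ground truth with trials", {
  tr <- canonical_model(sinusoid(300, 2, 0.6))
  err_at <- function(n) {
    sur <- surrogate_cap(tr, n_trials = n, noise_gain = 0.3, seed = 9)
    est <- instantaneous_amplitude(colMeans(sur$trials))
    interior <- 1000:5000
    mean(abs(est[interior] - sur$envelope[interior]))
  }
  expect_lt(err_at(200), err_at(20))
})
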