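test_that("a LIF without input or noise stays silent", {
  p <- lif_params()
  sd_ <- simulate_lif(p, rep(0, 1000), duration = 0.5)
  expect_equal(nrow(sd_$events), 0)
})

test_that("regular-LIF interspike intervals match the closed form", {
  p <- lif_params(sigma_stim = 1, sigma_noise = 0)
  for (I in c(1.5, 2, 4)) {
    sd_ <- simulate_lif(p, rep(I, 1), duration = 0.5)
    isi <- diff(sd_$events$time_s)
    pred <- p$tau_V * log(I / (I - p$V_thres))
    expect_lt(abs(mean(isi) - pred), 2 * p$dt)
  }
})

test_that("the adaptation current slows firing over successive spikes", {
  p <- lif_params(sigma_stim = 1, delta_A = 1)
  sd_ <- simulate_lif(p, rep(4, 1), duration = 0.3)
  isi <- diff(sd_$events$time_s)
  expect_true(all(diff(isi[1:5]) > 0))  # rate strictly decreasing early on
})

test_that("non-finite input is rejected and seeding reproduces spikes", {
  p <- lif_params(sigma_noise = 0.5)
  expect_error(simulate_lif(p, c(1, NA, 1), duration = 0.1), "non-finite")
  a <- simulate_lif(p, rep(1.2, 1), duration = 0.5, seed = 5)
  b <- simulate_lif(p, rep(1.2, 1), duration = 0.5, seed = 5)
  expect_identical(a$events, b$events)
})

test_that("population policies behave: empty, shared-noise synchrony,
           range fractionation gating", {
  p <- lif_params(sigma_noise = 0.3)
  stim_fn <- function(s) lif_noise(0.4, 1.5, mean_offset = 0.5, seed = s)

  empty <- simulate_population(0, p, stim_fn, "independent_realizations")
  expect_equal(nrow(empty$events), 0)

  shared <- simulate_population(40, p, stim_fn(1),
                                "shared_plus_private_noise", seed = 2)
  indep <- simulate_population(40, p, stim_fn,
                               "independent_realizations", seed = 2)
  # a shared stimulus locks neurons to common fluctuations: the population
  # rate is burstier than with independent realizations
  cv_bins <- function(s) {
    ps <- population_summary(s, bin = 0.002)
    stats::sd(ps$psth) / mean(ps$psth)
  }
  expect_gt(cv_bins(shared), cv_bins(indep))

  sched <- intensity_schedule(c(0, 0.2), c(1, 2))
  st <- lif_noise(0.4, sched, seed = 3)
  frac <- simulate_population(20, p, st, "range_fractionation", seed = 4)
  lo_pop <- frac$events$neuron <= 10
  expect_true(all(frac$events$time_s[lo_pop] <= 0.2 + 0.01))

  expect_error(simulate_population(5, p, stim_fn(1), "range_fractionation"),
               "intensity levels")
})

test_that("population summaries integrate counts and scale with n", {
  ev1 <- data.frame(neuron = 1L, trial = 1L, time_s = 0.05)
  sd1 <- spike_data(ev1, 1L, 1L, 0.1, 5e-5)
  ps1 <- population_summary(sd1, bin = 0.001)
  expect_equal(sum(ps1$psth), 1)

  ev2 <- rbind(ev1, transform(ev1, neuron = 2L))
  sd2 <- spike_data(ev2, 2L, 1L, 0.1, 5e-5)
  ps2 <- population_summary(sd2, bin = 0.001)
  expect_equal(ps2$psth, 2 * ps1$psth)

  ps0 <- population_summary(spike_data(ev1[0, ], 1L, 1L, 0.1, 5e-5))
  expect_equal(ps0$n_spikes, 0)
  expect_true(all(ps0$psth == 0))
  expect_true(is.na(ps0$synchrony_sd_s))
})
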