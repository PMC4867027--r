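test_that("rectangular smoothing behaves like a moving average", {
  tr <- voltage_trace(rep(3.5, 100), dt = 0.1)
  expect_equal(smooth_trace(tr, 2)$samples, rep(3.5, 100))
  # unit impulse spreads into a boxcar that sums to 1
  imp <- voltage_trace(c(rep(0, 50), 1, rep(0, 49)), dt = 0.1)
  sm <- smooth_trace(imp, 2)
  expect_equal(sum(sm$samples), 1, tolerance = 1e-12)
  expect_equal(max(sm$samples), 1 / 20, tolerance = 1e-12)
  # white-noise variance is reduced by ~dt/window
  set.seed(81)
  ns <- voltage_trace(stats::rnorm(20000), dt = 0.1)
  v <- stats::var(smooth_trace(ns, 2)$samples)
  expect_equal(v, 0.1 / 2, tolerance = 0.1)
  expect_error(smooth_trace(tr, 0.01), "window")
})

test_that("membrane time constant is recovered from falling edges", {
  dt <- 0.1
  t <- seq(0, 100, by = dt)
  pure <- voltage_trace(2 * exp(-t / 20), dt)
  expect_equal(estimate_membrane_tau(pure, list(c(0, 80))), 20,
               tolerance = 1e-3)
  # two windows with tau 18 and 22 average to 20
  two <- voltage_trace(c(exp(-t / 18), exp(-t / 22)), dt)
  tau <- estimate_membrane_tau(two, list(c(0, 60), c(100.1, 160)))
  expect_equal(tau, 20, tolerance = 0.05)
  # noisy exponential (SNR ~ 20) recovered within 5%
  set.seed(82)
  noisy <- voltage_trace(2 * exp(-t / 20) + stats::rnorm(length(t), 0, 0.05),
                         dt)
  expect_equal(estimate_membrane_tau(noisy, list(c(0, 60))), 20,
               tolerance = 0.05)
  expect_error(estimate_membrane_tau(pure, list(c(95, 95.2))),
               "falling-edge")
})

test_that("deconvolution annihilates the membrane kernel", {
  dt <- 0.05
  t <- seq(0, 60, by = dt)
  # constant voltage: RI = V
  cst <- voltage_trace(rep(1.3, length(t)), dt)
  expect_equal(deconvolve_trace(cst, 15)$samples, rep(1.3, length(t)))
  # pure membrane decay: RI ~ 0 away from the edges
  dec <- voltage_trace(2 * exp(-t / 15), dt)
  ri <- deconvolve_trace(dec, 15)$samples
  expect_lt(max(abs(ri[3:(length(t) - 2)])), 1e-4)
  # two overlapping EPSPs deconvolve into separated narrow pulses
  v <- simulate_voltage_trace(c(0.8, 0.5), c(10, 18), tau_m = 15, dt = dt)
  ri2 <- deconvolve_trace(v, 15)$samples
  tt <- stpem:::trace_times(v)
  p1 <- max(ri2[tt >= 9.8 & tt <= 11])
  p2 <- max(ri2[tt >= 17.8 & tt <= 19])
  trough <- max(abs(ri2[tt >= 16 & tt <= 17.7]))
  expect_gt(p1, 10 * trough)
  expect_gt(p2, 5 * trough)
})

test_that("crop/reconvolve peak extraction recovers known amplitudes", {
  dt <- 0.05
  amps <- c(0.9, 0.55, 0.35, 0.6)
  times <- c(20, 60, 100, 140)
  v <- simulate_voltage_trace(amps, times, tau_m = 12, dt = dt, t_end = 200)
  got <- extract_peaks(v, 12, times)
  expect_equal(got, amps, tolerance = 0.02 * max(amps))
  # zero trace gives zero amplitudes
  z <- voltage_trace(rep(0, 4001), dt)
  expect_equal(extract_peaks(z, 12, times), rep(0, 4))
  expect_error(extract_peaks(v, 12, c(20, 25)), "overlap")
})

test_that("baseline noise variance is pooled across pre-response windows", {
  dt <- 0.05
  z <- voltage_trace(rep(0, 2001), dt)
  expect_equal(baseline_noise_variance(z, c(20, 60)), 0)
  set.seed(83)
  n <- voltage_trace(stats::rnorm(20001, 0, 0.05), dt)
  v <- baseline_noise_variance(rep(list(n), 5), seq(100, 900, by = 100))
  expect_equal(v, 0.0025, tolerance = 0.15)
  expect_error(baseline_noise_variance(z, c(0.2)), "window")
})

test_that("end-to-end: simulated traces reproduce the generating amplitudes", {
  set.seed(84)
  p <- facilitating_params(sigma_n = 0)
  st <- spike_train(seq(0, 350, by = 50))
  sim <- simulate_trial(p, st)
  amps <- pmax(sim$amplitudes, 0.02)
  v <- simulate_voltage_trace(amps, st$times + 20, tau_m = 14, dt = 0.05,
                              t_end = 450)
  got <- extract_peaks(v, 14, st$times + 20)
  expect_equal(got, amps, tolerance = 0.02 * max(amps))
})

test_that("baseline drift detector warns on drifting traces", {
  dt <- 0.1
  t <- seq(0, 1000, by = dt)
  expect_warning(detect_baseline_drift(voltage_trace(0.002 * t, dt)), "drift")
  expect_silent(detect_baseline_drift(voltage_trace(rep(0.1, length(t)), dt)))
})
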