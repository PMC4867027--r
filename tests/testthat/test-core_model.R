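test_that("docking probability follows 1 - exp(-delta/tau_D)", {
  expect_identical(docking_probability(0, 670), 0)
  expect_equal(docking_probability(670, 670), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(docking_probability(670, 670), 0.6321206, tolerance = 1e-6)
  # monotone saturation toward 1
  d <- docking_probability(c(10, 50, 100, 400, 1500), 250)
  expect_true(all(diff(d) > 0))
  expect_lt(max(d), 1)
  expect_gt(docking_probability(1e4, 250), 1 - 1e-6)
  expect_lte(docking_probability(1e4, 250), 1)
  expect_error(docking_probability(-1, 100), "non-negative")
  expect_error(docking_probability(10, -5))
})

test_that("release-probability recursion and its limits", {
  u <- release_probability_sequence(0.3, 570, spike_train(c(0, 200)))
  expect_equal(u, c(0.3, 0.4478547), tolerance = 1e-6)
  # tau_F = 0: facilitation decays instantly
  expect_equal(release_probability_sequence(0.4, 0, c(0, 10, 20)),
               rep(0.4, 3))
  # intervals much longer than tau_F: full recovery to U
  u <- release_probability_sequence(0.2, 50, c(0, 5000, 10000))
  expect_equal(u[2], 0.2, tolerance = 1e-10)
  # all u in (0, 1]
  u <- release_probability_sequence(0.95, 800, seq(0, 400, by = 20))
  expect_true(all(u > 0 & u <= 1))
})

test_that("occupancy recursion and its limits", {
  p <- synaptic_parameters(10, 0.15, 0.03, 0.25, 670, 0)
  expect_equal(occupancy_sequence(p, c(0, 200)), c(1, 0.8145188),
               tolerance = 1e-6)
  # tau_D = 0: instantaneous refill
  p0 <- synaptic_parameters(5, 0.1, 0.02, 0.5, 0, 100)
  expect_equal(occupancy_sequence(p0, c(0, 10, 20)), rep(1, 3))
  # U -> 0 limit: nothing released, occupancy stays 1
  pu <- synaptic_parameters(5, 0.1, 0.02, 1e-12, 300, 0)
  expect_equal(occupancy_sequence(pu, c(0, 50, 100)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("mean responses equal A u x and match simulation averages", {
  p <- facilitating_params(sigma_n = 0)
  st <- regular_train()
  tr <- deterministic_trajectory(p, st)
  expect_equal(tr$mean_responses[1], 0.45, tolerance = 1e-12)  # N q U
  expect_equal(tr$mean_responses, p$N * p$q * tr$u * tr$x)
  expect_true(all(tr$mean_responses > 0 & tr$mean_responses <= p$A))
  # simulation oracle: trial means converge to the deterministic means
  set.seed(71)
  sims <- replicate(4000, simulate_trial(p, st)$amplitudes)
  mc <- rowMeans(sims)
  mc_se <- apply(sims, 1, stats::sd) / sqrt(ncol(sims))
  expect_true(all(abs(mc - tr$mean_responses) < 4 * mc_se + 1e-3))
})

test_that("u and x depend only on interspike intervals", {
  p <- facilitating_params()
  t1 <- c(0, 40, 160, 700)
  t2 <- t1 + 12345
  expect_equal(deterministic_trajectory(p, t1)$u,
               deterministic_trajectory(p, t2)$u)
  expect_equal(deterministic_trajectory(p, t1)$x,
               deterministic_trajectory(p, t2)$x)
})

test_that("regular-train monotonicity when time constants exceed the ISI", {
  p <- synaptic_parameters(8, 0.2, 0.04, 0.2, tau_D = 2000, tau_F = 2000)
  st <- spike_train(seq(0, 350, by = 50))
  tr <- deterministic_trajectory(p, st)
  expect_true(all(diff(tr$u) >= 0))
  expect_true(all(diff(tr$x) <= 0))
})

test_that("parameter container validates and serializes", {
  p <- synaptic_parameters(10, 0.15, 0.03, 0.3, 195, 570, 0.02)
  expect_equal(p$A, 1.5)
  expect_error(synaptic_parameters(0, 0.1, 0.01, 0.5, 100, 100))
  expect_error(synaptic_parameters(5, -0.1, 0.01, 0.5, 100, 100))
  expect_error(synaptic_parameters(5, 0.1, 0.01, 1.5, 100, 100))
  expect_error(synaptic_parameters(5, 0.1, 0.01, 0, 100, 100))
  lst <- params_to_list(p)
  expect_named(lst, c("N", "q", "sigma_q", "U", "tau_D", "tau_F", "sigma_n"))
  p2 <- params_from_list(lst)
  expect_equal(params_to_list(p2), lst)
})

test_that("spike trains require strictly increasing times", {
  expect_error(spike_train(c(0, 50, 50)), "strictly increasing")
  expect_error(spike_train(numeric(0)))
  st <- spike_train(c(0, 30, 90))
  expect_equal(st$intervals, c(30, 60))
})
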