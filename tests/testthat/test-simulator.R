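test_that("release and docking kernels match exact binomial pmfs", {
  set.seed(11)
  n <- 20000
  # release: S- = 2, u = 0.5
  sp <- replicate(n, sample_release(2, 0.5))
  emp <- tabulate(sp + 1, 3) / n
  expect_equal(emp, stats::dbinom(2:0, 2, 0.5), tolerance = 0.02)
  # docking: N = 2, S+ = 0, l = 0.5
  sm <- replicate(n, sample_docking(0, 2, 0.5))
  emp <- tabulate(sm + 1, 3) / n
  expect_equal(emp, stats::dbinom(0:2, 2, 0.5), tolerance = 0.02)
  # degenerate limits
  expect_equal(sample_release(3, 0), 3)
  expect_equal(sample_release(3, 1), 0)
  expect_equal(sample_docking(1, 4, 0), 1)
  expect_equal(sample_docking(1, 4, 1 - 1e-15), 4)
})

test_that("quantal response moments follow the inverse-Gaussian model", {
  set.seed(12)
  q <- 0.15; sq <- 0.05; sn <- 0.02
  x1 <- rinvgauss_quantal(50000, 1, q, sq)
  expect_equal(mean(x1), q, tolerance = 0.01)
  expect_equal(stats::var(x1), sq^2, tolerance = 0.05)
  # m vesicles + noise: mean m q, variance m sq^2 + sn^2
  m <- 4
  xm <- replicate(20000, sample_response(m, q, sq, sn))
  expect_equal(mean(xm), m * q, tolerance = 0.01)
  expect_equal(stats::var(xm), m * sq^2 + sn^2, tolerance = 0.05)
  # zero-vesicle, zero-noise case is exactly 0
  expect_identical(sample_response(0, q, sq, 0), 0)
})

test_that("simulated trials start fully recovered and respect the support", {
  set.seed(13)
  p <- depressing_params()
  st <- regular_train()
  for (i in 1:20) {
    sim <- simulate_trial(p, st)
    expect_identical(sim$s_minus[1], p$N)
    expect_true(all(sim$s_plus <= sim$s_minus))
    expect_true(all(sim$s_minus[-1] >= sim$s_plus[-length(sim$s_plus)]))
    expect_true(all(sim$s_minus <= p$N & sim$s_plus >= 0))
  }
})

test_that("single-spike failure probability equals (1-U)^N", {
  set.seed(14)
  p <- synaptic_parameters(4, 0.2, 0.03, 0.35, 300, 100, sigma_n = 0)
  fails <- replicate(20000, {
    simulate_trial(p, spike_train(0))$amplitudes[1] == 0
  })
  expect_equal(mean(fails), (1 - 0.35)^4, tolerance = 0.02)
})

test_that("regular protocol lays out train plus recovery spike", {
  spec <- stimulation_protocol("regular", T = 50, n_spikes = 8, n_trials = 3)
  trains <- make_protocol(spec)
  expect_length(trains, 3)
  expect_equal(trains[[1]]$times, c(seq(0, 350, by = 50), 900))
})

test_that("poisson protocol has exponential intervals of the right mean", {
  spec <- stimulation_protocol("poisson", T = 80, n_spikes = 8, n_trials = 400)
  trains <- make_protocol(spec, seed = 15)
  isi <- unlist(lapply(trains, function(st) st$intervals[1:7]))
  expect_equal(mean(isi), 80, tolerance = 0.05 * 80)
  # recovery interval fixed at T + 500
  rec <- vapply(trains, function(st) st$intervals[8], numeric(1))
  expect_equal(rec, rep(580, length(rec)), tolerance = 1e-12)
})

test_that("single-sweep blocks share the boundary spike", {
  spec <- stimulation_protocol("single_sweep", T = 200, n_spikes = 8,
                               duration_ms = 118000)
  trains <- make_protocol(spec, seed = 16)
  expect_length(trains, 1)
  times <- trains[[1]]$times
  # one response per spike; block structure: 1 + 8 k spikes total
  expect_equal((length(times) - 1) %% 8, 0)
  expect_lte(max(times), 118000)
  expect_error(make_protocol(
    stimulation_protocol("single_sweep", T = 200, n_spikes = 8,
                         duration_ms = 100)),
    "duration too short")
})

test_that("identical seed and spec give identical datasets", {
  p <- facilitating_params()
  spec <- stimulation_protocol("poisson", T = 100, n_spikes = 5, n_trials = 4)
  d1 <- simulate_dataset(p, spec, seed = 99)
  d2 <- simulate_dataset(p, spec, seed = 99)
  expect_identical(d1$trials, d2$trials)
  d3 <- simulate_dataset(p, spec, seed = 100)
  expect_false(identical(d1$trials, d3$trials))
})

test_that("depressing connections get noisier late in the train", {
  set.seed(17)
  ds <- simulate_dataset(depressing_params(), regular_train()$times |>
                           list() |> rep(400))
  cv <- cv_by_position(ds)
  # CV of late in-train responses exceeds the first response's CV
  expect_gt(mean(cv[6:8]), cv[1])
})

test_that("population sampler respects the documented ranges", {
  pop <- sample_population_connections(50, seed = 18)
  N <- vapply(pop, `[[`, numeric(1), "N")
  U <- vapply(pop, `[[`, numeric(1), "U")
  tF <- vapply(pop, `[[`, numeric(1), "tau_F")
  expect_true(all(N >= 2 & N <= 77))
  expect_true(all(U >= 0.05 & U <= 0.73))
  expect_true(all(tF >= 10 & tF <= 1900))
})
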