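test_that("forward-backward equals brute-force enumeration (property)", {
  set.seed(31)
  for (i in 1:30) {
    p <- random_small_params()
    st <- random_small_train()
    sim <- simulate_trial(p, st)
    fb <- forward_pass(sim$amplitudes, st, p)
    bf <- brute_force_log_likelihood(sim$amplitudes, st, p)
    expect_lt(rel_diff(fb$log_likelihood, bf), 1e-9)
  }
})

test_that("alpha starts as a point mass at the fully recovered state", {
  p <- facilitating_params()
  st <- regular_train()
  sim <- simulate_trial(p, st)
  fb <- forward_pass(sim$amplitudes, st, p)
  expect_equal(fb$alpha_minus[1, ], c(rep(0, p$N), 1))
})

test_that("forward-backward consistency identities hold at every spike", {
  set.seed(32)
  p <- synaptic_parameters(6, 0.18, 0.05, 0.35, 250, 300, sigma_n = 0.04)
  st <- regular_train()
  sim <- simulate_trial(p, st)
  fb <- backward_pass(sim$amplitudes, st, p)
  M <- length(st$times)
  # terminal condition: beta+ = 1 at the last spike
  expect_equal(fb$beta_plus[M, ], rep(1, p$N + 1))
  # scaled identities: sum_S alpha * beta = 1 at every spike
  for (k in seq_len(M)) {
    expect_equal(sum(fb$alpha_plus[k, ] * fb$beta_plus[k, ]), 1,
                 tolerance = 1e-9)
    expect_equal(sum(fb$alpha_minus[k, ] * fb$beta_minus[k, ]), 1,
                 tolerance = 1e-9)
  }
})

test_that("pair posteriors normalize, respect support, match enumeration", {
  set.seed(33)
  for (i in 1:8) {
    p <- random_small_params()
    st <- random_small_train(3)
    sim <- simulate_trial(p, st)
    post <- pair_posteriors(sim$amplitudes, st, p)
    bf <- stpem:::brute_force_enumeration(sim$amplitudes, st, p)
    K <- p$N + 1
    for (k in 1:3) {
      expect_equal(sum(post[k, , ]), 1, tolerance = 1e-10)
      # S+ > S- entries exactly zero
      for (smi in 1:K) for (spi in 1:K)
        if (spi > smi) expect_identical(post[k, smi, spi], 0)
    }
    expect_lt(max(abs(post - bf$pairs)), 1e-9)
  }
})

test_that("dataset log-likelihood adds over independent trials", {
  set.seed(34)
  p <- facilitating_params()
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 50,
                                                 n_spikes = 4, n_trials = 6))
  ll <- dataset_log_likelihood(ds, p)
  per <- dataset_log_likelihood(ds, p, by_trial = TRUE)
  expect_equal(ll, sum(per))
  # permutation invariance
  ds2 <- ds; ds2$trials <- rev(ds2$trials)
  expect_equal(dataset_log_likelihood(ds2, p), ll)
  # additivity over disjoint subsets
  dsA <- ds; dsA$trials <- ds$trials[1:2]
  dsB <- ds; dsB$trials <- ds$trials[3:6]
  expect_equal(dataset_log_likelihood(dsA, p) + dataset_log_likelihood(dsB, p),
               ll, tolerance = 1e-10)
  # two identical trials double the single-trial value
  dsC <- ds; dsC$trials <- ds$trials[c(1, 1)]
  expect_equal(dataset_log_likelihood(dsC, p), 2 * per[1], tolerance = 1e-10)
})

test_that("deterministic single-vesicle chain reduces to emission products", {
  # N = 1, U = 1, intervals >> tau_D: every spike releases exactly one vesicle
  p <- synaptic_parameters(1, 0.2, 0.04, 1, tau_D = 1, tau_F = 0,
                           sigma_n = 0.03)
  st <- spike_train(c(0, 500, 1000))
  R <- c(0.22, 0.18, 0.2)
  ll <- forward_pass(R, st, p)$log_likelihood
  ll_direct <- sum(log(vapply(R, emission_density, numeric(1),
                              s_minus = 1, s_plus = 0, q = 0.2,
                              sigma_q = 0.04, sigma_n = 0.03)))
  expect_equal(ll, ll_direct, tolerance = 1e-6)
})

test_that("enumeration oracle refuses oversized instances", {
  p <- synaptic_parameters(10, 0.15, 0.03, 0.3, 200, 200, sigma_n = 0.02)
  expect_error(brute_force_log_likelihood(rep(0.2, 3), c(0, 50, 100), p),
               "too large")
})

test_that("an impossible response strictly decreases the log-likelihood", {
  p <- synaptic_parameters(2, 0.2, 0.03, 0.5, 300, 100, sigma_n = 0.03)
  st <- spike_train(c(0, 50))
  base <- brute_force_log_likelihood(c(0.2, 0.2), st, p)
  far <- brute_force_log_likelihood(c(0.2, 5), st, p)
  expect_lt(far, base - 100)
})

test_that("likelihood is continuous in the continuous parameters", {
  set.seed(35)
  p <- synaptic_parameters(4, 0.2, 0.05, 0.4, 300, 200, sigma_n = 0.04)
  st <- regular_train()
  sim <- simulate_trial(p, st)
  ll0 <- forward_pass(sim$amplitudes, st, p)$log_likelihood
  for (nm in c("q", "sigma_q", "U", "tau_D", "tau_F")) {
    h <- 1e-7 * p[[nm]]
    p2 <- p; p2[[nm]] <- p2[[nm]] + h
    p2 <- do.call(synaptic_parameters,
                  p2[c("N", "q", "sigma_q", "U", "tau_D", "tau_F", "sigma_n")])
    ll1 <- forward_pass(sim$amplitudes, st, p2)$log_likelihood
    expect_lt(abs(ll1 - ll0), 1e-3 * max(1, abs(ll0)))
  }
})

test_that("misaligned responses and spikes are rejected", {
  p <- facilitating_params()
  expect_error(forward_pass(c(0.1, 0.2), c(0, 50, 100), p), "match")
})
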