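test_that("E-step expectations match brute-force posterior sums", {
  set.seed(41)
  for (i in 1:6) {
    p <- random_small_params()
    st <- random_small_train(2)
    sim <- simulate_trial(p, st)
    ds <- response_dataset(list(list(times = st$times,
                                     amplitudes = sim$amplitudes)),
                           sigma_n = p$sigma_n)
    es <- e_step(ds, p)
    g <- es$groups[[1]]
    bf <- stpem:::brute_force_enumeration(sim$amplitudes, st, p)
    S <- 0:p$N
    for (k in 1:2) {
      slice <- bf$pairs[k, , ]
      expect_lt(abs(g$E_s_minus[k] - sum(rowSums(slice) * S)), 1e-9)
      expect_lt(abs(g$E_s_plus[k] - sum(colSums(slice) * S)), 1e-9)
      m_post <- sum(outer(S, S, "-") * slice)
      expect_lt(abs(g$E_released[k] - m_post), 1e-9)
    }
    expect_true(all(g$E_s_minus >= 0 & g$E_s_minus <= p$N))
    expect_true(all(g$E_s_plus >= 0 & g$E_s_plus <= p$N))
    expect_true(all(g$E_released >= -1e-12))
  }
})

test_that("quantal update solves the stationarity condition in closed form", {
  set.seed(42)
  p <- facilitating_params()
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 50,
                                                 n_spikes = 8, n_trials = 30))
  es <- e_step(ds, p)
  p2 <- m_step(es, ds, p)
  # q_new = sum of posterior-mean latent responses / expected released count
  expect_equal(p2$q, es$Sa / es$Sm, tolerance = 1e-12)
  # in the noiseless limit the same update reads sum(R) / sum(<m>)
  p0 <- facilitating_params(sigma_n = 0)
  ds0 <- simulate_dataset(p0, stimulation_protocol("regular", T = 50,
                                                   n_spikes = 8,
                                                   n_trials = 30), seed = 5)
  # guard: noiseless estimation needs all responses positive
  ok <- all(unlist(lapply(ds0$trials, `[[`, "amplitudes")) > 0)
  if (ok) {
    es0 <- e_step(ds0, p0)
    p20 <- m_step(es0, ds0, p0)
    expect_equal(p20$q,
                 sum(unlist(lapply(ds0$trials, `[[`, "amplitudes"))) / es0$Sm,
                 tolerance = 1e-9)
  }
})

test_that("M step is a fixed point at an EM stationary point", {
  set.seed(43)
  p <- synaptic_parameters(4, 0.2, 0.05, 0.4, 250, 150, sigma_n = 0.04)
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 60,
                                                 n_spikes = 6, n_trials = 25))
  fit <- fit_fixed_N(ds, 4, restarts = 1, tol = 1e-10, max_iter = 1000)
  es <- e_step(ds, fit$params_hat)
  p2 <- m_step(es, ds, fit$params_hat)
  for (nm in c("q", "sigma_q", "U", "tau_D", "tau_F"))
    expect_equal(p2[[nm]], fit$params_hat[[nm]], tolerance = 1e-3)
})

test_that("EM log-likelihood is non-decreasing on diverse datasets", {
  set.seed(44)
  cases <- list(
    list(p = facilitating_params(),
         proto = stimulation_protocol("regular", T = 50, n_spikes = 8,
                                      n_trials = 12)),
    list(p = depressing_params(),
         proto = stimulation_protocol("poisson", T = 100, n_spikes = 6,
                                      n_trials = 10)))
  for (cs in cases) {
    ds <- simulate_dataset(cs$p, cs$proto)
    fit <- fit_fixed_N(ds, cs$p$N, restarts = 2)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-9 * pmax(1, abs(tr[-1]))))
  }
})

test_that("EM recovers the generating parameters on a large dataset", {
  set.seed(45)
  p <- synaptic_parameters(3, 0.2, 0.05, 0.4, 300, 150, sigma_n = 0.03)
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 50,
                                                 n_spikes = 8,
                                                 n_trials = 300))
  fit <- fit_fixed_N(ds, 3, restarts = 3)
  expect_equal(fit$params_hat$q, p$q, tolerance = 0.15)
  expect_equal(fit$params_hat$U, p$U, tolerance = 0.2)
  expect_equal(fit$params_hat$tau_D, p$tau_D, tolerance = 0.35)
  expect_true(fit$converged)
})

test_that("independent restarts agree on a well-conditioned dataset", {
  set.seed(46)
  p <- synaptic_parameters(3, 0.2, 0.05, 0.4, 300, 150, sigma_n = 0.03)
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 50,
                                                 n_spikes = 8,
                                                 n_trials = 60))
  f1 <- fit_fixed_N(ds, 3, restarts = 1)
  f2 <- fit_fixed_N(ds, 3,
                    init = synaptic_parameters(3, 0.1, 0.02, 0.6, 120, 400,
                                               sigma_n = 0.03),
                    restarts = 1)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-4)
})

test_that("model-order scan selects near the generating N and keeps profile", {
  set.seed(47)
  p <- synaptic_parameters(5, 0.2, 0.04, 0.4, 250, 200, sigma_n = 0.03)
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 50,
                                                 n_spikes = 8,
                                                 n_trials = 120))
  fit <- suppressWarnings(fit_em(ds, N_range = 2:10, restarts = 2,
                                 fresh_inits = FALSE, scan_from = 5))
  expect_true(abs(fit$params_hat$N - 5) <= 2)
  expect_true(all(c("N", "log_likelihood", "q") %in%
                    names(fit$per_N_profile)))
  expect_equal(nrow(fit$per_N_profile), 9)
  # profile peaks at the selected N
  expect_equal(fit$per_N_profile$N[which.max(fit$per_N_profile$log_likelihood)],
               fit$params_hat$N)
})

test_that("default scan covers N = 1..100 and sigma_n must be known", {
  expect_equal(eval(formals(fit_em)$N_range), 1:100)
  p <- facilitating_params()
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 50,
                                                 n_spikes = 4, n_trials = 5))
  ds$sigma_n <- NA_real_
  expect_error(fit_fixed_N(ds, 5), "sigma_n")
})
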