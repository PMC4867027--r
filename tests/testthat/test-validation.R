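test_that("position-preserving shuffle keeps marginals, kills correlations", {
  set.seed(71)
  p <- depressing_params()
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 50,
                                                 n_spikes = 8,
                                                 n_trials = 200))
  sh <- shuffle_within_position(ds, seed = 72)
  A <- do.call(rbind, lapply(ds$trials, `[[`, "amplitudes"))
  B <- do.call(rbind, lapply(sh$trials, `[[`, "amplitudes"))
  # per-position multisets (hence means and CVs) preserved exactly
  for (j in seq_len(ncol(A)))
    expect_equal(sort(A[, j]), sort(B[, j]))
  expect_equal(cv_by_position(ds), cv_by_position(sh))
  # lag-1 within-train correlation (position means removed) shrinks toward 0
  lag1 <- function(M) {
    Mc <- scale(M, center = TRUE, scale = FALSE)
    stats::cor(as.vector(Mc[, -ncol(Mc)]), as.vector(Mc[, -1]))
  }
  expect_lt(abs(lag1(B)), abs(lag1(A)))
  # ragged trials rejected
  ds2 <- ds
  ds2$trials[[1]]$times <- ds2$trials[[1]]$times + 1
  expect_error(shuffle_within_position(ds2), "skeleton")
})

test_that("cv_by_position matches a hand-computed table", {
  trials <- list(list(times = c(0, 50), amplitudes = c(1.0, 0.4)),
                 list(times = c(0, 50), amplitudes = c(1.2, 0.5)),
                 list(times = c(0, 50), amplitudes = c(0.8, 0.6)))
  ds <- response_dataset(trials)
  cv <- cv_by_position(ds)
  expect_equal(unname(cv[1]), stats::sd(c(1.0, 1.2, 0.8)) / 1.0)
  expect_equal(unname(cv[2]), stats::sd(c(0.4, 0.5, 0.6)) / 0.5)
  # identical responses across trials give CV 0
  ds0 <- response_dataset(rep(list(list(times = c(0, 50),
                                        amplitudes = c(0.7, 0.3))), 3))
  expect_equal(unname(cv_by_position(ds0)), c(0, 0), ignore_attr = TRUE)
})

test_that("parametric bootstrap summarizes relative errors and correlations", {
  set.seed(73)
  p <- synaptic_parameters(3, 0.2, 0.05, 0.4, 250, 150, sigma_n = 0.03)
  boot <- parametric_bootstrap(p, stimulation_protocol("regular", T = 50,
                                                       n_spikes = 6,
                                                       n_trials = 25),
                               n_reps = 6, seed = 74, scan_halfwidth = 2)
  expect_equal(nrow(boot$relative_errors) + boot$n_failed, 6)
  expect_true(all(boot$relative_errors >= -1))  # positive parameters
  expect_equal(diag(boot$correlations), rep(1, 6), ignore_attr = TRUE)
  expect_equal(boot$correlations, t(boot$correlations))
  expect_named(boot$bias, c("N", "q", "sigma_q", "U", "tau_D", "tau_F"))
})

test_that("correlation pooling Fisher-transforms before averaging", {
  C1 <- matrix(c(1, 0.8, 0.8, 1), 2)
  C2 <- matrix(c(1, 0.2, 0.2, 1), 2)
  pooled <- average_correlations(list(C1, C2))
  expect_equal(pooled[1, 2], tanh((atanh(0.8) + atanh(0.2)) / 2))
  expect_equal(diag(pooled), c(1, 1))
})

test_that("leave-one-out z_out lies in [0,1] and is calibrated on-model", {
  set.seed(75)
  p <- synaptic_parameters(3, 0.25, 0.05, 0.5, 300, 100, sigma_n = 0.04)
  ds <- simulate_dataset(p, stimulation_protocol("regular", T = 60,
                                                 n_spikes = 5,
                                                 n_trials = 8))
  z <- leave_one_out_zout(ds, N_range = 3, n_mc = 300, seed = 76)
  expect_true(all(z$z_out >= 0 & z$z_out <= 1, na.rm = TRUE))
  expect_s3_class(z$ks, "htest")
  # on-model data should not be flagged at the 1% level
  expect_true(z$uniform_at_0.01)
  expect_error(leave_one_out_zout(
    response_dataset(list(list(times = 0, amplitudes = 0.1),
                          list(times = 0, amplitudes = 0.2))), N_range = 2))
})
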