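# shared fixtures: the two illustrative connections (facilitating and
# depressing) and small protocol builders

facilitating_params <- function(sigma_n = 0.03)
  synaptic_parameters(N = 10, q = 0.15, sigma_q = 0.03, U = 0.3,
                      tau_D = 195, tau_F = 570, sigma_n = sigma_n)

depressing_params <- function(sigma_n = 0.03)
  synaptic_parameters(N = 10, q = 0.15, sigma_q = 0.03, U = 0.25,
                      tau_D = 670, tau_F = 15, sigma_n = sigma_n)

# the worked-example connection used for uncertainty quantification
worked_example_params <- function(sigma_n = 0.03)
  synaptic_parameters(N = 17, q = 0.18, sigma_q = 0.06, U = 0.27,
                      tau_D = 202, tau_F = 449, sigma_n = sigma_n)

# 8-spike regular train at `hz` plus recovery spike T_rec = T + 500 ms
regular_train <- function(hz = 20, n_spikes = 8) {
  T <- 1000 / hz
  spike_train(c(seq(0, by = T, length.out = n_spikes),
                (n_spikes - 1) * T + T + 500))
}

random_small_params <- function(sigma_n = NULL) {
  N <- sample(1:3, 1)
  synaptic_parameters(N, stats::runif(1, 0.1, 0.3), stats::runif(1, 0.02, 0.08),
                      stats::runif(1, 0.1, 0.9), stats::runif(1, 50, 800),
                      stats::runif(1, 0, 600),
                      sigma_n = if (is.null(sigma_n))
                        stats::runif(1, 0.02, 0.08) else sigma_n)
}

random_small_train <- function(M = sample(1:4, 1)) {
  t <- sort(stats::runif(M, 0, 500))
  spike_train(t + seq_along(t) * 1e-3)  # enforce strict increase
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
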