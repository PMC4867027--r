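#' Vesicle docking probability over an interval
#'
#' Probability that a non-competent release site becomes release competent
#' (a vesicle docks) within an interval `delta`, given the docking time
#' constant `tau_D`: `l(delta) = 1 - exp(-delta / tau_D)`.
#'
#' @param delta interval, ms (>= 0).  Vectorized.
#' @param tau_D docking time constant, ms (> 0; `tau_D = 0` is treated as the
#'   instantaneous-refill limit, `l = 1` for `delta > 0`).
#' @return docking probability in `[0, 1)` (or 1 in the `tau_D = 0` limit).
#' @examples
#' docking_probability(670, 670)  # 1 - exp(-1)
#' @export
docking_probability <- function(delta, tau_D) {
  if (any(delta < 0)) stop("'delta' must be non-negative")
  if (length(tau_D) != 1L || tau_D < 0) stop("'tau_D' must be a scalar >= 0")
  if (tau_D == 0) return(ifelse(delta > 0, 1, 0))
  -expm1(-delta / tau_D)
}

#' Release-probability sequence along a spike train
#'
#' Facilitation dynamics of the release probability: `u_1 = U` and
#' `u_{k+1} = U + u_k (1 - U) exp(-Delta_k / tau_F)`.  `tau_F = 0` is the
#' exact no-facilitation limit `u_k = U`.
#'
#' @param U initial release probability, in (0, 1].
#' @param tau_F facilitation time constant, ms (>= 0).
#' @param spikes a [spike_train] (or numeric vector of spike times, ms).
#' @return numeric vector `u_1..u_M`, all in (0, 1].
#' @examples
#' release_probability_sequence(0.3, 570, spike_train(c(0, 200)))
#' @export
release_probability_sequence <- function(U, tau_F, spikes) {
  spikes <- as_spike_train(spikes)
  M <- length(spikes$times)
  u <- numeric(M)
  u[1] <- U
  if (M > 1) {
    decay <- if (tau_F <= 0) rep(0, M - 1) else exp(-spikes$intervals / tau_F)
    for (k in seq_len(M - 1))
      u[k + 1] <- U + u[k] * (1 - U) * decay[k]
  }
  u
}

#' Site-occupancy sequence along a spike train
#'
#' Mean occupancy (probability that a site is release competent just before
#' each spike): `x_1 = 1` and
#' `x_{k+1} = 1 - [1 - (1 - u_k) x_k] exp(-Delta_k / tau_D)`.
#'
#' @param params a [synaptic_parameters] object.
#' @param spikes a [spike_train] (or numeric spike times, ms).
#' @return numeric vector `x_1..x_M`, all in (0, 1].
#' @export
occupancy_sequence <- function(params, spikes) {
  spikes <- as_spike_train(spikes)
  u <- release_probability_sequence(params$U, params$tau_F, spikes)
  M <- length(spikes$times)
  x <- numeric(M)
  x[1] <- 1
  if (M > 1) {
    decay <- if (params$tau_D <= 0) rep(0, M - 1)
             else exp(-spikes$intervals / params$tau_D)
    for (k in seq_len(M - 1))
      x[k + 1] <- 1 - (1 - (1 - u[k]) * x[k]) * decay[k]
  }
  x
}

#' Mean response sequence
#'
#' Average postsynaptic response per spike, `Rbar_k = N q u_k x_k` (the
#' absolute synaptic efficacy `A = N q` times release probability and
#' occupancy).
#'
#' @inheritParams occupancy_sequence
#' @return numeric vector of mean amplitudes, mV.
#' @export
mean_response_sequence <- function(params, spikes) {
  spikes <- as_spike_train(spikes)
  u <- release_probability_sequence(params$U, params$tau_F, spikes)
  x <- occupancy_sequence(params, spikes)
  params$N * params$q * u * x
}

#' Deterministic trajectory of the model
#'
#' Bundles the release-probability sequence `u`, the occupancy sequence `x`,
#' the per-interval docking probabilities `l` and the mean responses for a
#' spike train.
#'
#' @inheritParams occupancy_sequence
#' @return An object of class `deterministic_trajectory`: list with `u`, `x`,
#'   `l` (length M-1), and `mean_responses`.
#' @export
deterministic_trajectory <- function(params, spikes) {
  spikes <- as_spike_train(spikes)
  u <- release_probability_sequence(params$U, params$tau_F, spikes)
  x <- occupancy_sequence(params, spikes)
  l <- if (length(spikes$times) > 1)
    docking_probability(spikes$intervals, params$tau_D) else numeric(0)
  structure(list(u = u, x = x, l = l,
                 mean_responses = params$N * params$q * u * x,
                 times = spikes$times),
            class = "deterministic_trajectory")
}
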