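# Generative simulator: hidden release/docking paths and observable response
# trains under the stochastic TM model, plus the three stimulation protocols
# (regular, Poisson, single-sweep) used for protocol comparison.

#' Response dataset container
#'
#' @param trials list of trials, each a list with `times` (spike times, ms)
#'   and `amplitudes` (response amplitudes, mV, one per spike).
#' @param protocol optional protocol descriptor (list).
#' @param params optional generating [synaptic_parameters] (synthetic data).
#' @param sigma_n baseline noise SD used/assumed, mV.
#' @param seed optional integer seed recorded in the metadata.
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(trials, protocol = NULL, params = NULL,
                             sigma_n = NA_real_, seed = NULL) {
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    st <- as_spike_train(tr$times)
    if (length(tr$amplitudes) != length(st$times))
      stop(sprintf("trial %d: %d responses for %d spikes", i,
                   length(tr$amplitudes), length(st$times)))
    trials[[i]] <- list(times = st$times,
                        amplitudes = as.numeric(tr$amplitudes))
  }
  structure(list(trials = trials, protocol = protocol, params = params,
                 sigma_n = sigma_n, seed = seed),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  nr <- sum(vapply(x$trials, function(tr) length(tr$amplitudes), numeric(1)))
  cat(sprintf("Response dataset: %d trials, %d responses\n",
              length(x$trials), nr))
  if (!is.null(x$protocol$kind))
    cat(sprintf("  protocol: %s\n", x$protocol$kind))
  invisible(x)
}

#' Sample the release transition
#'
#' Number of release-competent sites after a spike: each of the `s_minus`
#' competent sites releases independently with probability `u`, so
#' `S+ = s_minus - Binomial(s_minus, u)`.
#'
#' @param s_minus competent sites before the spike.
#' @param u release probability.
#' @return sampled `S+` count.
#' @export
sample_release <- function(s_minus, u) {
  s_minus - stats::rbinom(length(s_minus), s_minus, u)
}

#' Sample the docking transition
#'
#' Number of competent sites just before the next spike: each of the
#' `N - s_plus` empty sites refills independently with probability `l`
#' during the interval, so `S- = s_plus + Binomial(N - s_plus, l)`.
#'
#' @param s_plus competent sites after the spike.
#' @param N total number of release sites.
#' @param l docking probability for the interval (see
#'   [docking_probability()]).
#' @return sampled next `S-` count.
#' @export
sample_docking <- function(s_plus, N, l) {
  s_plus + stats::rbinom(length(s_plus), N - s_plus, l)
}

#' Sample a postsynaptic response amplitude
#'
#' For `n_released >= 1` vesicles the amplitude is inverse-Gaussian with mean
#' `m q` and variance `m sigma_q^2` (linear summation), plus Gaussian baseline
#' noise of SD `sigma_n`; for `n_released = 0` it is pure baseline noise.
#'
#' @param n_released number of vesicles released (scalar, >= 0).
#' @param q,sigma_q quantal size and SD, mV.
#' @param sigma_n baseline noise SD, mV.
#' @return amplitude, mV.
#' @export
sample_response <- function(n_released, q, sigma_q, sigma_n) {
  base <- if (sigma_n > 0) stats::rnorm(1, 0, sigma_n) else 0
  if (n_released == 0) return(base)
  if (sigma_q <= 0) return(n_released * q + base)
  rinvgauss_quantal(1, n_released, q, sigma_q) + base
}

#' Simulate one trial
#'
#' Alternates release and docking transitions along the spike train, starting
#' from the fully recovered state `S-_1 = N`, and emits one response per
#' spike.
#'
#' @param params a [synaptic_parameters] object.
#' @param spikes a [spike_train] or numeric spike times, ms.
#' @return list with `amplitudes` (mV), and the hidden path `s_minus`,
#'   `s_plus` (site counts per spike).
#' @export
simulate_trial <- function(params, spikes) {
  spikes <- as_spike_train(spikes)
  ti <- trial_inputs(params, spikes)
  M <- ti$M
  s_minus <- integer(M); s_plus <- integer(M)
  amplitudes <- numeric(M)
  s <- params$N
  for (k in seq_len(M)) {
    s_minus[k] <- s
    sp <- sample_release(s, ti$u[k])
    s_plus[k] <- sp
    amplitudes[k] <- sample_response(s - sp, params$q, params$sigma_q,
                                     params$sigma_n)
    s <- if (k < M) sample_docking(sp, params$N, ti$l[k]) else sp
  }
  list(amplitudes = amplitudes, s_minus = s_minus, s_plus = s_plus)
}

#' Stimulation protocol descriptor
#'
#' The three protocols compared in the package: `regular` trains of
#' `n_spikes` at interval `T` followed by a recovery spike `T_rec` after the
#' last train spike; `poisson`, the same skeleton with i.i.d. exponential
#' within-train intervals of mean `T` (recovery interval kept fixed); and
#' `single_sweep`, Poisson blocks concatenated so that the recovery spike of
#' one block is the first spike of the next (the shared boundary response is
#' counted once), filling a requested recording duration.
#'
#' @param kind one of `"regular"`, `"poisson"`, `"single_sweep"`.
#' @param T mean interspike interval, ms.
#' @param n_spikes spikes per train (excluding the recovery spike).
#' @param T_rec recovery interval, ms; default `T + 500` as in paired
#'   recordings.
#' @param inter_trial_interval interval between the recovery spike of one
#'   trial and the first spike of the next, ms (regular/poisson).
#' @param n_trials number of trials (regular/poisson); alternatively
#'   `duration_ms` may be given and converts to a trial count.
#' @param duration_ms total recording duration, ms (required for
#'   `single_sweep`; optional otherwise).
#' @return An object of class `stimulation_protocol` (a list).
#' @export
stimulation_protocol <- function(kind = c("regular", "poisson", "single_sweep"),
                                 T = 50, n_spikes = 8, T_rec = T + 500,
                                 inter_trial_interval = 4000,
                                 n_trials = NULL, duration_ms = NULL) {
  kind <- match.arg(kind)
  if (kind == "single_sweep" && is.null(duration_ms))
    stop("single_sweep protocol requires 'duration_ms'")
  if (kind != "single_sweep" && is.null(n_trials) && is.null(duration_ms))
    stop("specify 'n_trials' or 'duration_ms'")
  structure(list(kind = kind, T = T, n_spikes = n_spikes, T_rec = T_rec,
                 inter_trial_interval = inter_trial_interval,
                 n_trials = n_trials, duration_ms = duration_ms),
            class = "stimulation_protocol")
}

#' Generate the spike trains of a protocol
#'
#' @param spec a [stimulation_protocol].
#' @param seed optional integer; seeds the global RNG (recorded downstream).
#' @return list of [spike_train] objects (one per trial; a single long train
#'   for the single-sweep protocol).
#' @export
make_protocol <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "stimulation_protocol"))
  if (!is.null(seed)) set.seed(seed)
  n_sp <- spec$n_spikes
  if (spec$kind == "regular") {
    n_tr <- protocol_trial_count(spec)
    times <- c(seq(0, by = spec$T, length.out = n_sp),
               (n_sp - 1) * spec$T + spec$T_rec)
    return(replicate(n_tr, spike_train(times), simplify = FALSE))
  }
  if (spec$kind == "poisson") {
    n_tr <- protocol_trial_count(spec)
    return(lapply(seq_len(n_tr), function(i) {
      isi <- stats::rexp(n_sp - 1, rate = 1 / spec$T)
      spike_train(cumsum(c(0, isi, spec$T_rec)))
    }))
  }
  # single sweep: blocks of n_spikes with exponential ISIs; the block's last
  # interval is the fixed recovery interval leading into the next block's
  # first spike (shared boundary spike).
  dur <- spec$duration_ms
  times <- 0
  repeat {
    isi <- c(stats::rexp(n_sp - 1, rate = 1 / spec$T), spec$T_rec)
    block <- times[length(times)] + cumsum(isi)
    if (block[length(block)] > dur) {
      if (length(times) == 1)
        stop("duration too short for a single block")
      break
    }
    times <- c(times, block)
  }
  list(spike_train(times))
}

# number of trials implied by a regular/poisson spec
protocol_trial_count <- function(spec) {
  if (!is.null(spec$n_trials)) return(spec$n_trials)
  span <- (spec$n_spikes - 1) * spec$T + spec$T_rec + spec$inter_trial_interval
  n <- floor(spec$duration_ms / span)
  if (n < 1) stop("duration too short for one trial")
  n
}

#' Simulate a synthetic experiment
#'
#' Generates the spike trains of a protocol and one response train per trial
#' under the generative model; doubles as the fixture generator for the test
#' suite.
#'
#' @param params a [synaptic_parameters] object.
#' @param protocol a [stimulation_protocol], or a list of spike trains /
#'   numeric time vectors to use directly.
#' @param seed optional integer seed (recorded in the dataset metadata).
#' @param keep_hidden logical; keep the simulated hidden paths.
#' @return a [response_dataset]; if `keep_hidden`, each trial also carries
#'   `s_minus` and `s_plus`.
#' @export
simulate_dataset <- function(params, protocol, seed = NULL,
                             keep_hidden = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  trains <- if (inherits(protocol, "stimulation_protocol"))
    make_protocol(protocol) else lapply(protocol, as_spike_train)
  trials <- lapply(trains, function(st) {
    sim <- simulate_trial(params, st)
    tr <- list(times = st$times, amplitudes = sim$amplitudes)
    if (keep_hidden) { tr$s_minus <- sim$s_minus; tr$s_plus <- sim$s_plus }
    tr
  })
  ds <- response_dataset(trials,
                         protocol = if (inherits(protocol,
                                                 "stimulation_protocol"))
                           unclass(protocol) else NULL,
                         params = params, sigma_n = params$sigma_n,
                         seed = seed)
  if (keep_hidden)
    for (i in seq_along(trials)) ds$trials[[i]] <- trials[[i]]
  ds
}

#' Sample synthetic connections from the population distributions
#'
#' Draws parameter sets from truncated normal distributions matching the
#' population mean, SD and range of the estimates reported for layer-5
#' pyramidal-pair recordings (N 15+-12 in 2..77, q 0.15+-0.06 mV in
#' 0.06..0.32, sigma_q 0.05+-0.05 mV, U 0.33+-0.13 in 0.05..0.73,
#' tau_D 335+-306 ms in 16..1800, tau_F 321+-340 ms clipped below at 10 ms
#' to remain identifiable).  Baseline noise is fixed at `sigma_n`.
#'
#' @param n number of connections.
#' @param sigma_n baseline noise SD, mV.
#' @param seed optional integer seed.
#' @return list of [synaptic_parameters].
#' @export
sample_population_connections <- function(n, sigma_n = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    pmin(pmax(x, lo), hi)
  }
  lapply(seq_len(n), function(i)
    synaptic_parameters(
      N = round(rtnorm(1, 15, 12, 2, 77)),
      q = rtnorm(1, 0.15, 0.06, 0.06, 0.32),
      sigma_q = rtnorm(1, 0.05, 0.05, 0.01, 0.31),
      U = rtnorm(1, 0.33, 0.13, 0.05, 0.73),
      tau_D = rtnorm(1, 335, 306, 16, 1800),
      tau_F = rtnorm(1, 321, 340, 10, 1900),
      sigma_n = sigma_n))
}
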