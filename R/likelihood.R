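# Exact likelihood of a response train under the stochastic TM model.
# The hidden chain is the number of release-competent sites immediately
# before (S-) and after (S+) each spike; the forward-backward recursions sum
# the joint probability over all hidden paths in O(M N^2).

# deterministic per-train inputs for the engine: u_k, l_k and, if requested,
# their parameter derivatives
trial_inputs <- function(params, spikes, derivatives = FALSE) {
  spikes <- as_spike_train(spikes)
  M <- length(spikes$times)
  u <- release_probability_sequence(params$U, params$tau_F, spikes)
  l <- if (M > 1) docking_probability(spikes$intervals, params$tau_D)
       else numeric(0)
  out <- list(u = u, l = l, M = M, times = spikes$times)
  if (derivatives) {
    U <- params$U; tF <- params$tau_F; tD <- params$tau_D
    duU <- numeric(M); dutF <- numeric(M)
    duU[1] <- 1
    if (M > 1) {
      dec <- if (tF <= 0) rep(0, M - 1) else exp(-spikes$intervals / tF)
      for (k in seq_len(M - 1)) {
        duU[k + 1] <- 1 + dec[k] * (duU[k] * (1 - U) - u[k])
        dutF[k + 1] <- dec[k] * ((1 - U) * dutF[k] +
          if (tF > 0) u[k] * (1 - U) * spikes$intervals[k] / tF^2 else 0)
      }
    }
    dltD <- if (M > 1 && tD > 0)
      -(spikes$intervals / tD^2) * exp(-spikes$intervals / tD)
    else rep(0, max(M - 1, 0))
    out$du_dU <- duU; out$du_dtF <- dutF; out$dl_dtD <- dltD
  }
  out
}

fb_engine <- function(responses, spikes, params,
                      tables = FALSE, pairs = FALSE, stats = FALSE,
                      gl = default_gl_rule()) {
  spikes <- as_spike_train(spikes)
  responses <- as.numeric(responses)
  if (length(responses) != length(spikes$times))
    stop("number of responses (", length(responses),
         ") does not match number of spikes (", length(spikes$times), ")")
  ti <- trial_inputs(params, spikes)
  .cpp_fb_trial(responses, ti$u, ti$l, params$N, params$q,
                max(params$sigma_q, 1e-12), params$sigma_n,
                gl$nodes, gl$weights, tables, pairs, stats)
}

#' Forward pass: scaled alpha tables and log-likelihood
#'
#' Runs the scaled forward recursion over the hidden release-site counts and
#' returns the forward tables together with the log-likelihood of the
#' response train.  `alpha_minus[k, S+1]` is the scaled probability of state
#' `S` just before spike `k` given responses `1..k-1`; `alpha_plus` the
#' analogue just after the spike given responses `1..k`.  Underflow is
#' prevented by per-spike scaling constants (`log_scalers`), whose sum is the
#' log-likelihood.
#'
#' @param responses response amplitudes, mV (one per spike).
#' @param spikes a [spike_train] or numeric spike times, ms.
#' @param params a [synaptic_parameters] object.
#' @return An object of class `fb_tables` with elements `alpha_minus`,
#'   `alpha_plus`, `beta_minus`, `beta_plus` (scaled), `log_scalers`,
#'   `log_emission` and `log_likelihood`.
#' @export
forward_pass <- function(responses, spikes, params) {
  out <- fb_engine(responses, spikes, params, tables = TRUE)
  structure(out, class = "fb_tables")
}

#' Backward pass: scaled beta tables
#'
#' Companion of [forward_pass()]; the terminal condition is `beta_plus = 1`
#' at the last spike (no future observations).  With the shared per-spike
#' scaling, `sum_S alpha[k, S] * beta[k, S] = 1` at every spike.
#'
#' @inheritParams forward_pass
#' @return An object of class `fb_tables` (same fields as [forward_pass()]).
#' @export
backward_pass <- function(responses, spikes, params) {
  forward_pass(responses, spikes, params)
}

#' Posterior over hidden pair states
#'
#' Posterior probability `P(S-_k = s_minus, S+_k = s_plus | R_{1..M})` for
#' every spike, computed from the forward-backward tables.  Each spike's
#' slice sums to 1 and entries with `s_plus > s_minus` are exactly 0.
#'
#' @inheritParams forward_pass
#' @return array of dimension `M x (N+1) x (N+1)`; dimensions are
#'   (spike, S- + 1, S+ + 1).
#' @export
pair_posteriors <- function(responses, spikes, params) {
  out <- fb_engine(responses, spikes, params, pairs = TRUE)
  p <- out$pairs
  dimnames(p) <- list(NULL, paste0("sminus", 0:params$N),
                      paste0("splus", 0:params$N))
  p
}

#' Log-likelihood of a full dataset
#'
#' Trials are statistically independent, so the dataset log-likelihood is the
#' sum of per-trial log-likelihoods.
#'
#' @param dataset a [response_dataset].
#' @param params a [synaptic_parameters] object.
#' @param by_trial logical; if `TRUE` return the vector of per-trial values.
#' @return scalar log-likelihood (or per-trial vector).
#' @export
dataset_log_likelihood <- function(dataset, params, by_trial = FALSE) {
  stopifnot(inherits(dataset, "response_dataset"))
  ll <- vapply(dataset$trials, function(tr)
    fb_engine(tr$amplitudes, tr$times, params)$log_likelihood, numeric(1))
  if (by_trial) ll else sum(ll)
}

#' Brute-force likelihood by hidden-path enumeration
#'
#' Test oracle: sums the joint probability of the responses and every hidden
#' path over all `(N+1)^(2M)` candidate site-count sequences (infeasible ones
#' contribute 0).  Only small instances are accepted.  The emission densities
#' use the adaptive-quadrature [emission_density()], independent of the
#' engine's fixed rule.
#'
#' @inheritParams forward_pass
#' @param max_N,max_M enumeration bounds (defaults 4 and 4).
#' @return log-likelihood (scalar).
#' @export
brute_force_log_likelihood <- function(responses, spikes, params,
                                       max_N = 4, max_M = 4) {
  enum <- brute_force_enumeration(responses, spikes, params, max_N, max_M)
  enum$log_likelihood
}

# full enumeration: returns log-likelihood and pair posteriors
brute_force_enumeration <- function(responses, spikes, params,
                                    max_N = 4, max_M = 4) {
  spikes <- as_spike_train(spikes)
  N <- params$N
  M <- length(spikes$times)
  if (N > max_N || M > max_M)
    stop(sprintf("instance too large for enumeration (N <= %d, M <= %d)",
                 max_N, max_M))
  stopifnot(length(responses) == M)
  ti <- trial_inputs(params, spikes)
  # emission table: density of R_k given m released vesicles
  E <- matrix(0, M, N + 1)
  for (k in seq_len(M))
    for (m in 0:N)
      E[k, m + 1] <- emission_density(responses[k], m, 0, params$q,
                                      max(params$sigma_q, 1e-12),
                                      params$sigma_n)
  grid <- expand.grid(rep(list(0:N), 2 * M))  # sm1, sp1, sm2, sp2, ...
  sm <- as.matrix(grid[, seq(1, 2 * M, by = 2), drop = FALSE])
  sp <- as.matrix(grid[, seq(2, 2 * M, by = 2), drop = FALSE])
  prob <- as.numeric(sm[, 1] == N)  # initial condition: all sites competent
  for (k in seq_len(M)) {
    rel <- stats::dbinom(sm[, k] - sp[, k], sm[, k], ti$u[k])
    rel[sp[, k] > sm[, k]] <- 0
    m_idx <- pmax(sm[, k] - sp[, k], 0L)  # infeasible rows have rel = 0
    prob <- prob * rel * E[cbind(k, m_idx + 1L)]
    if (k < M) {
      dk <- stats::dbinom(sm[, k + 1] - sp[, k], N - sp[, k], ti$l[k])
      dk[sm[, k + 1] < sp[, k]] <- 0
      prob <- prob * dk
    }
  }
  L <- sum(prob)
  post <- array(0, dim = c(M, N + 1, N + 1))
  if (L > 0)
    for (k in seq_len(M)) {
      tab <- tapply(prob, list(factor(sm[, k], levels = 0:N),
                               factor(sp[, k], levels = 0:N)), sum)
      tab[is.na(tab)] <- 0
      post[k, , ] <- tab / L
    }
  list(log_likelihood = log(L), pairs = post)
}
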