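# Fisher-information analysis of stimulation protocols: score recursions,
# Monte-Carlo FIM, normalized Cramer-Rao bounds, and the central-limit-theorem
# minimum-repetition calculator.  N is discrete and excluded from the FIM;
# the matrix is over the continuous parameters (q, sigma_q, U, tau_D, tau_F).

FIM_PARAMS <- c("q", "sigma_q", "U", "tau_D", "tau_F")

#' Score vector of a response train
#'
#' Gradient of the log-likelihood with respect to the continuous parameters
#' `(q, sigma_q, U, tau_D, tau_F)`, computed by propagating the derivatives
#' of the forward variables alongside the scaled forward recursion (not by
#' finite differences).
#'
#' @inheritParams forward_pass
#' @return named numeric vector of length 5.
#' @export
score_vector <- function(responses, spikes, params) {
  spikes <- as_spike_train(spikes)
  responses <- as.numeric(responses)
  if (length(responses) != length(spikes$times))
    stop("responses and spikes misaligned")
  ti <- trial_inputs(params, spikes, derivatives = TRUE)
  gl <- default_gl_rule()
  s <- .cpp_score_trial(responses, ti$u, ti$l, ti$du_dU, ti$du_dtF, ti$dl_dtD,
                        params$N, params$q, max(params$sigma_q, 1e-12),
                        params$sigma_n, gl$nodes, gl$weights)
  if (any(!is.finite(s)))
    stop("non-finite score component: ",
         paste(FIM_PARAMS[!is.finite(s)], collapse = ", "))
  s
}

# score of a full multi-trial experiment (trials independent: scores add)
dataset_score <- function(dataset, params) {
  Reduce(`+`, lapply(dataset$trials, function(tr)
    score_vector(tr$amplitudes, tr$times, params)))
}

#' Monte-Carlo Fisher Information Matrix of a protocol
#'
#' Approximates the expected outer product of the score (the FIM) by
#' averaging over `n_mc` experiments simulated from the generative model
#' under the given protocol at the given parameters.
#'
#' @param params a [synaptic_parameters] (requires `sigma_n > 0`).
#' @param protocol a [stimulation_protocol], or a list of spike trains used
#'   as a fixed protocol.
#' @param n_mc Monte-Carlo sample count (default 1000).
#' @param seed integer seed.
#' @return An object of class `fim_result`: `matrix` (5x5, symmetric),
#'   `n_mc`, `seed`, `mean_score` (should be ~0 at the true parameters).
#' @export
fisher_information_matrix <- function(params, protocol, n_mc = 1000,
                                      seed = NULL) {
  stopifnot(n_mc >= 1)
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, 5, 5, dimnames = list(FIM_PARAMS, FIM_PARAMS))
  msum <- numeric(5)
  for (i in seq_len(n_mc)) {
    ds <- simulate_dataset(params, protocol)
    s <- dataset_score(ds, params)
    acc <- acc + tcrossprod(s)
    msum <- msum + s
  }
  structure(list(matrix = acc / n_mc, n_mc = n_mc, seed = seed,
                 mean_score = msum / n_mc, params = params),
            class = "fim_result")
}

#' Cramér–Rao lower bounds on relative estimation errors
#'
#' Normalized Cramér–Rao bound per continuous parameter:
#' `eps_j = sqrt([I^-1]_jj) / theta_j` (the diagonal of the inverse FIM lower
#' bounds the estimator variance).  A numerically singular FIM is inverted by
#' pseudo-inverse and the null directions are reported as `Inf` with a flag.
#'
#' @param fim a `fim_result` (or a plain 5x5 matrix).
#' @param params the [synaptic_parameters] at which the FIM was computed
#'   (defaults to those stored in `fim`).
#' @return named vector of relative-error lower bounds, with attribute
#'   `null_directions` naming non-identifiable parameters (if any).
#' @export
min_relative_errors <- function(fim, params = NULL) {
  I <- if (inherits(fim, "fim_result")) fim$matrix else as.matrix(fim)
  if (is.null(params) && inherits(fim, "fim_result")) params <- fim$params
  stopifnot(!is.null(params))
  theta <- c(params$q, params$sigma_q, params$U, params$tau_D, params$tau_F)
  sv <- svd(I)
  tol <- max(dim(I)) * max(sv$d) * .Machine$double.eps * 1e3
  pos <- sv$d > tol
  Iinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  vars <- diag(Iinv)
  null_dir <- character(0)
  if (any(!pos)) {
    null_load <- rowSums(abs(sv$v[, !pos, drop = FALSE]))
    null_dir <- FIM_PARAMS[null_load > 0.1]
    vars[FIM_PARAMS %in% null_dir] <- Inf
  }
  eps <- sqrt(pmax(vars, 0)) / theta
  names(eps) <- FIM_PARAMS
  attr(eps, "null_directions") <- null_dir
  eps
}

#' Minimum repetitions for a given precision of the average response
#'
#' Central-limit-theorem calculator: smallest integer n such that
#' `z * cv / sqrt(n) <= rel_precision`, with a three-standard-error criterion
#' by default (`z = 3` is the unique small multiplier consistent with the
#' usual "about 80 repetitions at 10% for CV 0.3, >300 at 5%" figures; it is
#' configurable).
#'
#' @param cv coefficient of variation of the response (>= 0).
#' @param rel_precision target relative precision of the average, in (0, 1).
#' @param z standard-error multiplier (default 3).
#' @return integer number of repetitions (minimum 1).
#' @examples
#' min_trials_for_precision(0.3, 0.10)  # 81
#' min_trials_for_precision(0.3, 0.05)  # 324
#' @export
min_trials_for_precision <- function(cv, rel_precision, z = 3) {
  stopifnot(cv >= 0, rel_precision > 0, rel_precision < 1)
  max(1L, as.integer(ceiling((z * cv / rel_precision)^2 - 1e-9)))
}

#' Compare stimulation protocols by Cramér–Rao bounds
#'
#' Computes the FIM-based relative-error lower bounds for each protocol in a
#' list, at the same parameters, and returns them as a table (one row per
#' protocol, one column per continuous parameter).
#'
#' @param params a [synaptic_parameters].
#' @param protocols named list of [stimulation_protocol] objects (or spike
#'   train lists).
#' @inheritParams fisher_information_matrix
#' @return data.frame of bounds; attribute `fims` holds the `fim_result`s.
#' @export
compare_protocols <- function(params, protocols, n_mc = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fims <- lapply(protocols, function(pr)
    fisher_information_matrix(params, pr, n_mc = n_mc))
  eps <- lapply(fims, min_relative_errors, params = params)
  out <- as.data.frame(do.call(rbind, eps))
  out <- cbind(protocol = names(protocols), out, row.names = NULL)
  attr(out, "fims") <- fims
  out
}
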