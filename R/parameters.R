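#' Synaptic parameter set for the stochastic Tsodyks-Markram model
#'
#' Container for the full parameter vector of the generative model of
#' repetitive synaptic transmission: `N` release sites, quantal size `q`,
#' quantal variability `sigma_q`, initial release probability `U`, docking
#' (recovery-from-depression) time constant `tau_D`, facilitation time
#' constant `tau_F`, and the SD `sigma_n` of the additive Gaussian baseline
#' noise of the recording.  Times are in milliseconds, amplitudes in
#' millivolts, throughout the package.
#'
#' `tau_F = 0` and `tau_D = 0` are accepted as exact limits (no facilitation:
#' `u_k = U`; instantaneous refill: `x_k = 1`) rather than errors, since
#' fitted values of 0 occur in real data.  `sigma_n = 0` is allowed for
#' simulation, but inference requires `sigma_n > 0` whenever release failures
#' can occur (the zero-vesicle emission is otherwise a point mass at 0).
#'
#' @param N integer >= 1, number of release sites.
#' @param q quantal size, mV (> 0).
#' @param sigma_q quantal SD, mV (>= 0).
#' @param U initial release probability, in (0, 1].
#' @param tau_D docking time constant, ms (>= 0; 0 means instantaneous).
#' @param tau_F facilitation time constant, ms (>= 0; 0 means none).
#' @param sigma_n baseline noise SD, mV (>= 0).
#'
#' @return An object of class `synaptic_parameters`: a named list with the
#'   seven fields above plus the derived absolute synaptic efficacy
#'   `A = N * q` (read-only).
#' @examples
#' p <- synaptic_parameters(N = 10, q = 0.15, sigma_q = 0.03,
#'                          U = 0.3, tau_D = 195, tau_F = 570)
#' p$A  # 1.5 mV
#' @export
synaptic_parameters <- function(N, q, sigma_q, U, tau_D, tau_F, sigma_n = 0) {
  N <- as.integer(round(N))
  stopifnot(length(N) == 1L, is.finite(N), N >= 1L)
  check_scalar <- function(x, nm, lo, lo_open = FALSE, hi = Inf) {
    if (length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite scalar", nm), call. = FALSE)
    if (x < lo || (lo_open && x == lo) || x > hi)
      stop(sprintf("'%s' = %g outside its admissible range", nm, x),
           call. = FALSE)
  }
  check_scalar(q, "q", 0, lo_open = TRUE)
  check_scalar(sigma_q, "sigma_q", 0)
  check_scalar(U, "U", 0, lo_open = TRUE, hi = 1)
  check_scalar(tau_D, "tau_D", 0)
  check_scalar(tau_F, "tau_F", 0)
  check_scalar(sigma_n, "sigma_n", 0)
  structure(
    list(N = N, q = q, sigma_q = sigma_q, U = U,
         tau_D = tau_D, tau_F = tau_F, sigma_n = sigma_n,
         A = N * q),
    class = "synaptic_parameters")
}

#' @export
print.synaptic_parameters <- function(x, ...) {
  cat("Stochastic TM synaptic parameters\n")
  cat(sprintf("  N = %d sites, q = %.4g mV, sigma_q = %.4g mV (A = %.4g mV)\n",
              x$N, x$q, x$sigma_q, x$A))
  cat(sprintf("  U = %.4g, tau_D = %.4g ms, tau_F = %.4g ms\n",
              x$U, x$tau_D, x$tau_F))
  cat(sprintf("  baseline noise sigma_n = %.4g mV\n", x$sigma_n))
  invisible(x)
}

#' Serialize parameters to / from a flat key-value block
#'
#' The flat representation uses exactly the field names
#' `N, q, sigma_q, U, tau_D, tau_F, sigma_n` and is the exchange format used
#' by the JSON/CSV interfaces.
#'
#' @param params a [synaptic_parameters] object.
#' @return `params_to_list()`: a named list of the seven scalar fields.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "synaptic_parameters"))
  params[c("N", "q", "sigma_q", "U", "tau_D", "tau_F", "sigma_n")]
}

#' @rdname params_to_list
#' @param x a named list (or 1-row data.frame) with the seven fields.
#' @return `params_from_list()`: a [synaptic_parameters] object.
#' @export
params_from_list <- function(x) {
  x <- as.list(x)
  need <- c("N", "q", "sigma_q", "U", "tau_D", "tau_F")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing parameter fields: ", paste(missing, collapse = ", "))
  synaptic_parameters(N = x$N, q = x$q, sigma_q = x$sigma_q, U = x$U,
                      tau_D = x$tau_D, tau_F = x$tau_F,
                      sigma_n = if (is.null(x$sigma_n)) 0 else x$sigma_n)
}

#' Presynaptic spike train
#'
#' @param times strictly increasing spike times, ms (length >= 1).
#' @return An object of class `spike_train` with elements `times` and the
#'   interspike intervals `intervals` (`Delta_k = t_{k+1} - t_k`).
#' @export
spike_train <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)))
    stop("spike times must be a non-empty finite numeric vector")
  d <- diff(times)
  if (any(d <= 0))
    stop("spike times must be strictly increasing")
  structure(list(times = times, intervals = d), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %.4g ms\n",
              length(x$times), diff(range(x$times))))
  invisible(x)
}

as_spike_train <- function(x) {
  if (inherits(x, "spike_train")) x else spike_train(x)
}
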