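# Preprocessing of raw postsynaptic voltage traces: smoothing, membrane
# time-constant estimation, deconvolution through the passive membrane
# equation RI(t) = tau_m dV/dt + V, crop/reconvolve peak extraction, and
# baseline-noise estimation.

#' Voltage trace container
#'
#' @param samples voltage samples, mV, uniformly spaced.
#' @param dt sampling interval, ms (> 0).
#' @param t0 time of the first sample, ms.
#' @return object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, dt, t0 = 0) {
  stopifnot(dt > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), dt = dt, t0 = t0),
            class = "voltage_trace")
}

trace_times <- function(trace)
  trace$t0 + (seq_along(trace$samples) - 1) * trace$dt

as_voltage_trace <- function(x, dt = NULL) {
  if (inherits(x, "voltage_trace")) return(x)
  if (is.null(dt)) stop("'dt' required for a plain numeric trace")
  voltage_trace(x, dt)
}

#' Smooth a voltage trace with a rectangular window
#'
#' Moving average with a rectangular window (default 2 ms); length is
#' preserved, with the window shrinking at the edges.
#'
#' @param trace a [voltage_trace].
#' @param window_ms window size, ms (>= `dt`).
#' @return smoothed [voltage_trace].
#' @export
smooth_trace <- function(trace, window_ms = 2) {
  trace <- as_voltage_trace(trace)
  if (window_ms < trace$dt) stop("window must be at least one sample wide")
  w <- max(1L, round(window_ms / trace$dt))
  n <- length(trace$samples)
  cs <- cumsum(c(0, trace$samples))
  half <- (w - 1) %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - 1 - half), n)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  voltage_trace(out, trace$dt, trace$t0)
}

#' Estimate the membrane time constant from falling edges
#'
#' Fits an exponential decay to each supplied falling-edge window of the
#' (typically trial-averaged) trace and returns the arithmetic mean of the
#' fitted time constants.  Windows whose fit does not decay are skipped.
#'
#' @param avg_trace a [voltage_trace].
#' @param fit_windows list of `c(start_ms, end_ms)` windows on the falling
#'   edges (recovery response; first response where possible).
#' @return estimated tau_m, ms.
#' @export
estimate_membrane_tau <- function(avg_trace, fit_windows) {
  avg_trace <- as_voltage_trace(avg_trace)
  tt <- trace_times(avg_trace)
  taus <- c()
  for (wnd in fit_windows) {
    sel <- tt >= wnd[1] & tt <= wnd[2]
    if (sum(sel) < 4) next
    t <- tt[sel] - wnd[1]
    v <- avg_trace$samples[sel]
    # log-linear seed on the clearly-above-noise part of the decay
    hiv <- v > 0.2 * max(v)
    if (sum(hiv) < 4) next
    lf <- stats::lm(log(v[hiv]) ~ t[hiv])
    tau0 <- -1 / stats::coef(lf)[2]
    if (!is.finite(tau0) || tau0 <= 0) next
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(v ~ a * exp(-t / tau), start = list(a = v[1], tau = tau0),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    tau <- if (is.null(fit)) tau0 else stats::coef(fit)[["tau"]]
    if (is.finite(tau) && tau > 0) taus <- c(taus, tau)
  }
  if (!length(taus)) stop("no usable falling-edge window")
  mean(taus)
}

#' Deconvolve a trace through the membrane equation
#'
#' Pointwise `RI(t) = tau_m dV/dt + V` with a central-difference derivative
#' (one-sided at the edges).
#'
#' @param trace a [voltage_trace].
#' @param tau_m membrane time constant, ms (> 0).
#' @return [voltage_trace] of RI values.
#' @export
deconvolve_trace <- function(trace, tau_m) {
  trace <- as_voltage_trace(trace)
  stopifnot(tau_m > 0)
  v <- trace$samples
  n <- length(v)
  dv <- numeric(n)
  if (n >= 3) dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * trace$dt)
  dv[1] <- (v[2] - v[1]) / trace$dt
  dv[n] <- (v[n] - v[n - 1]) / trace$dt
  voltage_trace(tau_m * dv + v, trace$dt, trace$t0)
}

# discrete inverse of the deconvolution: first-order exponential filter
reconvolve_trace <- function(ri, tau_m, dt, v0 = 0) {
  a <- exp(-dt / tau_m)
  v <- numeric(length(ri))
  prev <- v0
  for (i in seq_along(ri)) {
    prev <- prev * a + ri[i] * (1 - a)
    v[i] <- prev
  }
  v
}

#' Extract peak response amplitudes from a voltage trace
#'
#' Smooths and deconvolves the trace, crops a window (default 12 ms) centred
#' on each nominal stimulation time, reconvolves each crop through the
#' membrane kernel (yielding fully separated responses), and takes the peak
#' of each reconvolved crop.
#'
#' @param trace a [voltage_trace].
#' @param tau_m membrane time constant, ms.
#' @param nominal_spike_times stimulation times, ms.
#' @param crop_ms crop window width, ms (default 12).
#' @param smooth_ms smoothing window, ms (default 2).
#' @param sign +1 for EPSPs (peak = maximum), -1 for IPSPs.
#' @return numeric vector of response amplitudes, mV (one per spike).
#' @export
extract_peaks <- function(trace, tau_m, nominal_spike_times, crop_ms = 12,
                          smooth_ms = 2, sign = 1) {
  trace <- as_voltage_trace(trace)
  tt <- trace_times(trace)
  half <- crop_ms / 2
  st <- sort(nominal_spike_times)
  if (length(st) > 1 && any(diff(st) < crop_ms)) {
    bad <- which(diff(st) < crop_ms)
    stop("crops overlap for spike pairs: ",
         paste(sprintf("(%d,%d)", bad, bad + 1), collapse = " "))
  }
  if (st[1] - half < tt[1] || st[length(st)] + half > tt[length(tt)])
    stop("crop windows fall outside the trace extent")
  sm <- smooth_trace(trace, smooth_ms)
  ri <- deconvolve_trace(sm, tau_m)
  vapply(st, function(s) {
    sel <- tt >= s - half & tt <= s + half
    rec <- reconvolve_trace(ri$samples[sel], tau_m, trace$dt)
    sign * max(sign * rec)
  }, numeric(1))
}

#' Baseline noise variance from pre-response windows
#'
#' Variance of the voltage over a short window (default 1 ms) immediately
#' before each response onset, pooled across spikes and trials: one
#' `sigma_n^2` per connection.
#'
#' @param traces a [voltage_trace] or list of them (one per trial).
#' @param nominal_spike_times stimulation times, ms.
#' @param window_ms window length, ms (default 1).
#' @return pooled variance, mV^2.
#' @export
baseline_noise_variance <- function(traces, nominal_spike_times,
                                    window_ms = 1) {
  if (inherits(traces, "voltage_trace")) traces <- list(traces)
  segs <- list()
  for (trace in traces) {
    trace <- as_voltage_trace(trace)
    tt <- trace_times(trace)
    for (s in nominal_spike_times) {
      if (s - window_ms < tt[1] - 1e-9 || s > tt[length(tt)])
        stop("baseline window outside trace at t = ", s)
      sel <- tt >= s - window_ms & tt < s
      seg <- trace$samples[sel]
      segs[[length(segs) + 1]] <- seg - mean(seg)
    }
  }
  x <- unlist(segs)
  sum(x^2) / max(length(x) - length(segs), 1)
}

#' Detect linear baseline drift (advisory)
#'
#' Fits a line to the trace and warns when the fitted drift over the trace
#' duration exceeds `threshold_mv`.  Traces with drift should be excluded by
#' the caller; this is a warning, not a filter.
#'
#' @param trace a [voltage_trace].
#' @param threshold_mv drift magnitude triggering the warning, mV.
#' @return invisible drift estimate, mV (over the whole trace).
#' @export
detect_baseline_drift <- function(trace, threshold_mv = 0.5) {
  trace <- as_voltage_trace(trace)
  tt <- trace_times(trace)
  slope <- stats::coef(stats::lm(trace$samples ~ tt))[2]
  drift <- slope * diff(range(tt))
  if (is.finite(drift) && abs(drift) > threshold_mv)
    warning(sprintf("baseline drift of %.3g mV detected", drift))
  invisible(unname(drift))
}

#' Simulate a synthetic voltage trace (test fixture)
#'
#' Simple EPSP kernel for exercising the preprocessing pipeline: each
#' response follows a difference-of-exponentials kernel (rise `tau_rise`,
#' decay `tau_m`) normalized to the requested peak amplitude; Gaussian noise
#' is added per sample.  Synthetic stand-in for recorded traces; not a
#' biophysical simulation.
#'
#' @param amplitudes peak response amplitudes, mV (one per spike).
#' @param spike_times spike times, ms.
#' @param tau_m membrane (decay) time constant, ms.
#' @param tau_rise rise time constant, ms (must be < `tau_m`).
#' @param dt sampling interval, ms.
#' @param t_end trace end time, ms.
#' @param noise_sd per-sample noise SD, mV.
#' @return a [voltage_trace].
#' @export
simulate_voltage_trace <- function(amplitudes, spike_times, tau_m,
                                   tau_rise = tau_m / 10,
                                   dt = 0.1, t_end = NULL, noise_sd = 0) {
  stopifnot(length(amplitudes) == length(spike_times), tau_rise < tau_m)
  if (is.null(t_end)) t_end <- max(spike_times) + 10 * tau_m
  tt <- seq(0, t_end, by = dt)
  # peak of the un-normalized kernel exp(-t/tau_m) - exp(-t/tau_rise)
  tpk <- log(tau_m / tau_rise) * tau_m * tau_rise / (tau_m - tau_rise)
  pk <- exp(-tpk / tau_m) - exp(-tpk / tau_rise)
  v <- numeric(length(tt))
  for (i in seq_along(spike_times)) {
    s <- tt - spike_times[i]
    on <- s >= 0
    v[on] <- v[on] + amplitudes[i] / pk *
      (exp(-s[on] / tau_m) - exp(-s[on] / tau_rise))
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  voltage_trace(v, dt, 0)
}
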