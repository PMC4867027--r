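# Estimator diagnostics: parametric bootstrap (bias / SD / correlations of
# the estimates), leave-one-out predictive checks (z_out with a uniformity
# test), position-preserving shuffles, and per-position coefficients of
# variation.

PARAM_NAMES6 <- c("N", "q", "sigma_q", "U", "tau_D", "tau_F")

params_as_vector <- function(p) {
  c(N = p$N, q = p$q, sigma_q = p$sigma_q, U = p$U,
    tau_D = p$tau_D, tau_F = p$tau_F)
}

#' Parametric bootstrap of the EM estimates
#'
#' Simulates `n_reps` synthetic experiments from `params` with the same
#' settings (protocol, trial count, baseline noise), re-estimates all six
#' parameters by EM on each replicate, and summarizes the relative errors
#' with respect to the generating parameters.  By default the model-order
#' scan is restricted to `N +- scan_halfwidth` around the generating value
#' (clipped to 1..100), with `restarts = 1` per N and warm starts across the
#' scan — the full 1..100 scan is available via `full_scan = TRUE` at much
#' higher cost.
#'
#' @param params generating [synaptic_parameters] (with `sigma_n > 0`).
#' @param protocol a [stimulation_protocol] or list of spike trains.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed.
#' @param scan_halfwidth half-width of the restricted N scan (default 20).
#' @param full_scan scan N over 1..100 instead.
#' @param restarts EM restarts for the first N of each scan.
#' @param coarse_step step of the coarse model-order scan; the likelihood
#'   profile over N is smooth and unimodal in practice, so each replicate is
#'   scanned coarsely first (at a relaxed tolerance) and the winner refined
#'   by +-(coarse_step) at full tolerance.  Set to 1 for an exhaustive scan.
#' @return An object of class `bootstrap_result`: `relative_errors`
#'   (n_reps x 6), `bias`, `sd`, `correlations` (6x6 Pearson, of the raw
#'   estimates), `n_failed`, `n_reps`, `seed`.
#' @export
parametric_bootstrap <- function(params, protocol, n_reps = 500, seed = NULL,
                                 scan_halfwidth = 20, full_scan = FALSE,
                                 restarts = 1, coarse_step = 3) {
  stopifnot(n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  N_lo <- if (full_scan) 1 else max(1, params$N - scan_halfwidth)
  N_hi <- if (full_scan) 100 else min(100, params$N + scan_halfwidth)
  truth <- params_as_vector(params)
  est <- matrix(NA_real_, n_reps, 6, dimnames = list(NULL, PARAM_NAMES6))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    ds <- simulate_dataset(params, protocol)
    fit <- tryCatch(
      suppressWarnings(
        fit_em_scan(ds, N_lo, N_hi, coarse_step,
                    restarts = max(restarts, 3), anchor = params$N)),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    est[r, ] <- params_as_vector(fit$params_hat)
  }
  ok <- stats::complete.cases(est)
  rel <- sweep(est[ok, , drop = FALSE], 2, truth, "-")
  rel <- sweep(rel, 2, truth, "/")
  structure(list(relative_errors = rel,
                 bias = colMeans(rel),
                 sd = apply(rel, 2, stats::sd),
                 correlations = stats::cor(est[ok, , drop = FALSE]),
                 estimates = est,
                 n_failed = n_failed, n_reps = n_reps, seed = seed,
                 params = params),
            class = "bootstrap_result")
}

# coarse-to-fine model-order scan used by the resampling diagnostics: coarse
# grid at relaxed tolerance, then +-step refinement at full tolerance around
# the coarse winner (warm-started).
fit_em_scan <- function(dataset, N_lo, N_hi, step = 3, restarts = 3,
                        tol = 1e-8, sigma_n = NULL, anchor = NULL) {
  if (is.null(anchor)) anchor <- round((N_lo + N_hi) / 2)
  scan_tol <- max(1e-6, tol)
  if (step <= 1 || N_hi - N_lo <= 4) {
    sel <- fit_em(dataset, N_range = N_lo:N_hi, restarts = restarts,
                  tol = scan_tol, sigma_n = sigma_n, fresh_inits = FALSE,
                  scan_from = anchor, early_stop_drop = 6)
  } else {
    coarse_range <- unique(c(seq(N_lo, N_hi, by = step), N_hi))
    coarse <- fit_em(dataset, N_range = coarse_range, restarts = restarts,
                     tol = max(1e-5, tol), sigma_n = sigma_n,
                     fresh_inits = FALSE,
                     scan_from = anchor, early_stop_drop = 6)
    Nc <- coarse$params_hat$N
    refine_range <- max(N_lo, Nc - step + 1):min(N_hi, Nc + step - 1)
    sel <- fit_em(dataset, N_range = refine_range, init = coarse$params_hat,
                  restarts = 1, tol = scan_tol, sigma_n = sigma_n,
                  fresh_inits = FALSE, scan_from = Nc, early_stop_drop = 6)
    sel$coarse_profile <- coarse$per_N_profile
  }
  if (tol < scan_tol) {
    # polish only the selected model order at the full tolerance
    polish <- fit_fixed_N(dataset, sel$params_hat$N, init = sel$params_hat,
                          restarts = 1, tol = tol, sigma_n = sigma_n)
    polish$per_N_profile <- sel$per_N_profile
    polish$coarse_profile <- sel$coarse_profile
    polish$boundary_maximum <- sel$boundary_maximum
    return(polish)
  }
  sel
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: %d replicates (%d failed)\n",
              x$n_reps, x$n_failed))
  print(round(rbind(bias = x$bias, sd = x$sd), 4))
  invisible(x)
}

#' Pool correlation matrices across connections
#'
#' Fisher-transforms each correlation matrix, averages element-wise, and
#' transforms back — the aggregation used for estimate-correlation summaries
#' across a population of connections.
#'
#' @param cor_list list of correlation matrices of equal dimension.
#' @return pooled correlation matrix.
#' @export
average_correlations <- function(cor_list) {
  stopifnot(length(cor_list) >= 1)
  z <- lapply(cor_list, function(C) atanh(pmin(pmax(C, -1 + 1e-12),
                                               1 - 1e-12)))
  out <- tanh(Reduce(`+`, z) / length(z))
  diag(out) <- 1
  out
}

#' Leave-one-out predictive check (z_out)
#'
#' For each trial: refit on the remaining trials, simulate the fitted model's
#' distribution of single-trial log-likelihoods (Monte Carlo), and record
#' `z_out` — the probability that the model generates a trial with
#' log-likelihood equal to or smaller than that of the left-out trial
#' (empirical CDF, `<=` convention).  Under a correct model `z_out` is
#' uniform on [0, 1]; uniformity is assessed by a Kolmogorov-Smirnov test
#' (significance 0.01 by convention).
#'
#' @param dataset a [response_dataset] with at least 3 trials.
#' @param N_range N scan for the per-fold refits (a single value fixes N).
#' @param n_mc Monte-Carlo trials per fold (default 2000).
#' @param seed integer seed.
#' @param restarts EM restarts per fold.
#' @return An object of class `zout_result`: `z_out` (per trial), `ks`
#'   (the `ks.test` result), `uniform_at_0.01` flag, `skipped` fold indices.
#' @export
leave_one_out_zout <- function(dataset, N_range, n_mc = 2000, seed = NULL,
                               restarts = 1) {
  stopifnot(inherits(dataset, "response_dataset"),
            length(dataset$trials) >= 3)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dataset$trials)
  z <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    rest <- dataset
    rest$trials <- dataset$trials[-i]
    fit <- tryCatch(
      suppressWarnings(fit_em(rest, N_range = N_range, restarts = restarts)),
      error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, i)
      warning("refit failed for fold ", i, "; fold skipped")
      next
    }
    p <- fit$params_hat
    held <- dataset$trials[[i]]
    ll_held <- fb_engine(held$amplitudes, held$times, p)$log_likelihood
    ti <- trial_inputs(p, held$times)
    ll_sim <- vapply(seq_len(n_mc), function(s) {
      sim <- simulate_trial(p, spike_train(held$times))
      fb_engine(sim$amplitudes, held$times, p)$log_likelihood
    }, numeric(1))
    z[i] <- mean(ll_sim <= ll_held)
  }
  zz <- z[!is.na(z)]
  ks <- suppressWarnings(stats::ks.test(zz, "punif"))
  structure(list(z_out = z, ks = ks, uniform_at_0.01 = ks$p.value > 0.01,
                 skipped = skipped, n_mc = n_mc, seed = seed),
            class = "zout_result")
}

#' Shuffle responses across trials, preserving position
#'
#' Randomly reassigns responses to trials while keeping each response at its
#' position within the train (an independent permutation of trials at every
#' position).  Per-position means, SDs and CVs are exactly preserved; the
#' within-trial correlation structure is destroyed.  All trials must share
#' the same spike-train skeleton.
#'
#' @param dataset a [response_dataset].
#' @param seed integer seed.
#' @return a shuffled [response_dataset].
#' @export
shuffle_within_position <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "response_dataset"))
  if (!is.null(seed)) set.seed(seed)
  keys <- vapply(dataset$trials, function(tr) skeleton_key(tr$times),
                 character(1))
  if (length(unique(keys)) != 1L)
    stop("all trials must share the same spike-train skeleton")
  A <- do.call(rbind, lapply(dataset$trials, `[[`, "amplitudes"))
  for (j in seq_len(ncol(A)))
    A[, j] <- A[sample(nrow(A)), j]
  out <- dataset
  for (i in seq_len(nrow(A)))
    out$trials[[i]]$amplitudes <- A[i, ]
  out$protocol$shuffled <- TRUE
  out
}

#' Coefficient of variation per spike position
#'
#' SD across trials divided by the mean, per position within the train.  A
#' position with (numerically) zero mean is reported as `NA`.
#'
#' @param dataset a [response_dataset] with >= 2 trials sharing a skeleton.
#' @param recovery_index position treated as the recovery response (default:
#'   the last); reported via the `recovery` attribute.
#' @return named numeric vector of CVs; attribute `recovery` is the CV at
#'   the recovery position.
#' @export
cv_by_position <- function(dataset,
                           recovery_index = NULL) {
  stopifnot(inherits(dataset, "response_dataset"),
            length(dataset$trials) >= 2)
  keys <- vapply(dataset$trials, function(tr) skeleton_key(tr$times),
                 character(1))
  if (length(unique(keys)) != 1L)
    stop("all trials must share the same spike-train skeleton")
  A <- do.call(rbind, lapply(dataset$trials, `[[`, "amplitudes"))
  mu <- colMeans(A)
  s <- apply(A, 2, stats::sd)
  cv <- ifelse(abs(mu) < 1e-12, NA_real_, s / mu)
  names(cv) <- paste0("pos", seq_along(cv))
  if (is.null(recovery_index)) recovery_index <- length(cv)
  attr(cv, "recovery") <- cv[[recovery_index]]
  cv
}
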