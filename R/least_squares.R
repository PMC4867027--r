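# Conventional least-squares baseline: fit the deterministic mean responses
# A u_k x_k to trial-averaged data over theta_LS = (A, U, tau_D, tau_F).
# Only the product A = N q is identifiable from averages; the quantal
# parameters N, q, sigma_q are not resolved by this route.

ls_theta_names <- c("A", "U", "tau_D", "tau_F")

# model means at theta = c(A, U, tau_D, tau_F)
ls_mean <- function(theta, spikes) {
  p <- synaptic_parameters(N = 1, q = theta[1], sigma_q = 0, U = theta[2],
                           tau_D = theta[3], tau_F = theta[4])
  mean_response_sequence(p, spikes)
}

ls_to_trans <- function(theta)
  c(log(theta[1]), stats::qlogis(min(max(theta[2], 1e-8), 1 - 1e-8)),
    log(max(theta[3], 1e-3)), log(max(theta[4], 1e-3)))

ls_from_trans <- function(th) {
  th <- pmin(pmax(th, c(log(1e-6), -36, log(1e-4), log(1e-4))),
             c(log(1e4), 36, log(1e8), log(1e8)))
  c(exp(th[1]), stats::plogis(th[2]), exp(th[3]), exp(th[4]))
}

ls_wsse <- function(th, avg, w, spikes)
  sum((avg - ls_mean(ls_from_trans(th), spikes))^2 / w)

# Gauss-Newton polish in transformed coordinates; refines an optim solution
# to near machine precision so that finite-difference refits are stable.
ls_polish <- function(th, avg, w, spikes, iters = 10) {
  obj <- ls_wsse(th, avg, w, spikes)
  for (it in seq_len(iters)) {
    r <- avg - ls_mean(ls_from_trans(th), spikes)
    J <- matrix(0, length(avg), 4)
    for (j in 1:4) {
      h <- max(1e-7, 1e-7 * abs(th[j]))
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      J[, j] <- (ls_mean(ls_from_trans(tp), spikes) -
                 ls_mean(ls_from_trans(tm), spikes)) / (2 * h)
    }
    A <- crossprod(J, J / w)
    g <- crossprod(J, r / w)
    step <- tryCatch(solve(A + diag(1e-12, 4), g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- th + lam * as.numeric(step)
      val <- ls_wsse(cand, avg, w, spikes)
      if (val <= obj || lam < 1e-6) break
      lam <- lam / 2
    }
    if (val >= obj - 1e-18 * max(1, obj) && lam < 1e-6) break
    if (val < obj) { th <- cand; obj <- val } else break
  }
  list(th = th, value = obj)
}

ls_optimize <- function(avg, w, spikes, inits) {
  best <- NULL
  for (init in inits) {
    th0 <- ls_to_trans(init)
    o <- tryCatch(
      stats::optim(th0, ls_wsse, avg = avg, w = w, spikes = spikes,
                   method = "L-BFGS-B",
                   lower = c(log(1e-4), -16, log(1e-3), log(1e-3)),
                   upper = c(log(1e3), 16, log(1e7), log(1e7)),
                   control = list(maxit = 500, factr = 1e3)),
      error = function(e) NULL)
    if (is.null(o)) next
    p <- ls_polish(o$par, avg, w, spikes)
    if (is.null(best) || p$value < best$value) best <- p
  }
  best
}

#' Least-squares fit of mean responses
#'
#' Minimizes the weighted sum of squared differences between trial-averaged
#' responses and the model means over `(A, U, tau_D, tau_F)`, with bound
#' constraints enforced through log/logit transforms and a multi-start local
#' optimizer followed by a Gauss-Newton polish.
#'
#' @param avg_responses trial-averaged response per spike position, mV.
#' @param weights per-position variances `s_i^2` (all 1 for unweighted).
#' @param spikes a [spike_train] or numeric spike times, ms.
#' @param init optional initial `(A, U, tau_D, tau_F)` vector.
#' @param n_starts number of perturbed starts (default 5).
#' @return An object of class `lsf_result`: `params_ls` (named vector),
#'   `residual` (weighted SSE), `weights`, `spikes`.
#' @export
lsf_fit <- function(avg_responses, weights = NULL, spikes, init = NULL,
                    n_starts = 5) {
  spikes <- as_spike_train(spikes)
  avg <- as.numeric(avg_responses)
  M <- length(spikes$times)
  if (length(avg) != M) stop("positions do not match spikes")
  if (is.null(weights)) weights <- rep(1, M)
  if (length(weights) != M || any(weights <= 0))
    stop("weights must be positive, one per position")
  isi <- if (M > 1) exp(mean(log(diff(spikes$times)))) else 100
  base <- if (is.null(init)) c(max(max(avg), 1e-3) * 2, 0.3, isi, isi)
          else as.numeric(init)
  inits <- list(base)
  if (n_starts > 1)
    for (s in seq_len(n_starts - 1))
      inits[[s + 1]] <- c(base[1] * exp(stats::runif(1, log(1/3), log(3))),
                          min(max(base[2] * exp(stats::runif(1, log(1/3),
                                                             log(3))),
                                  0.02), 0.95),
                          base[3] * exp(stats::runif(1, log(1/3), log(3))),
                          base[4] * exp(stats::runif(1, log(1/3), log(3))))
  best <- ls_optimize(avg, weights, spikes, inits)
  if (is.null(best)) stop("least-squares optimization failed on all starts")
  theta <- ls_from_trans(best$th)
  names(theta) <- ls_theta_names
  structure(list(params_ls = theta, residual = best$value, weights = weights,
                 spikes = spikes, avg_responses = avg),
            class = "lsf_result")
}

#' @export
print.lsf_result <- function(x, ...) {
  cat(sprintf(
    "LSF: A = %.4g mV, U = %.4g, tau_D = %.4g ms, tau_F = %.4g ms (wSSE %.3g)\n",
    x$params_ls[1], x$params_ls[2], x$params_ls[3], x$params_ls[4],
    x$residual))
  invisible(x)
}

#' Sensitivity matrix of the least-squares mapping
#'
#' The least-squares fit maps average responses to parameter estimates; `D`
#' is its 4 x M Jacobian, `D[i, j] = d theta_i / d <R>_j`, evaluated by
#' central finite differences of warm-started refits around the model means
#' at `params_ls`.
#'
#' @param params_ls `(A, U, tau_D, tau_F)` vector (or an `lsf_result`).
#' @param spikes a [spike_train] or numeric spike times, ms.
#' @param weights per-position variances (default all 1: unweighted).
#' @param rel_step relative finite-difference step on each average response.
#' @return 4 x M matrix `D` (rows named A, U, tau_D, tau_F).
#' @export
sensitivity_matrix <- function(params_ls, spikes, weights = NULL,
                               rel_step = 1e-4) {
  if (inherits(params_ls, "lsf_result")) params_ls <- params_ls$params_ls
  spikes <- as_spike_train(spikes)
  theta <- as.numeric(params_ls)
  M <- length(spikes$times)
  if (is.null(weights)) weights <- rep(1, M)
  avg <- ls_mean(theta, spikes)
  th0 <- ls_to_trans(theta)
  refit <- function(a, j) {
    p <- ls_polish(th0, a, weights, spikes, iters = 20)
    if (!is.finite(p$value))
      stop("refit failed at perturbed position ", j)
    ls_from_trans(p$th)
  }
  D <- matrix(0, 4, M, dimnames = list(ls_theta_names, NULL))
  for (j in seq_len(M)) {
    h <- rel_step * max(abs(avg[j]), 1e-6)
    ap <- avg; ap[j] <- ap[j] + h
    am <- avg; am[j] <- am[j] - h
    D[, j] <- (refit(ap, j) - refit(am, j)) / (2 * h)
  }
  D
}

#' Condition number of the least-squares estimation
#'
#' `c = ||D||_2 * ||Rbar||_2 / ||theta_LS||_2`, with `D` the sensitivity
#' matrix, `Rbar` the model means at `params_ls` and the spectral norm for
#' the matrix.  Values much larger than 1 indicate an ill-posed fit: small
#' perturbations of the average responses cause disproportionate changes of
#' the estimates.  Evaluated with unit weights by default, so that `c` is a
#' function of the parameters and protocol alone.
#'
#' @inheritParams sensitivity_matrix
#' @return scalar condition number.
#' @export
condition_number <- function(params_ls, spikes, weights = NULL,
                             rel_step = 1e-4) {
  if (inherits(params_ls, "lsf_result")) params_ls <- params_ls$params_ls
  spikes <- as_spike_train(spikes)
  theta <- as.numeric(params_ls)
  D <- sensitivity_matrix(theta, spikes, weights, rel_step)
  rbar <- ls_mean(theta, spikes)
  nD <- svd(D, nu = 0, nv = 0)$d[1]
  nD * sqrt(sum(rbar^2)) / sqrt(sum(theta^2))
}

#' Perturbation range of the least-squares estimates
#'
#' Adds Gaussian noise with relative SD `noise_rel_sd` independently to each
#' model-mean response, refits, and reports, per parameter, the range
#' (max - min) of the relative errors across `n_reps` repetitions — the
#' noise-sensitivity experiment accompanying the condition-number analysis
#' (defaults: 1% noise, 15 repetitions).
#'
#' @inheritParams sensitivity_matrix
#' @param noise_rel_sd relative SD of the perturbing noise.
#' @param n_reps number of repetitions (>= 2).
#' @param seed optional integer seed.
#' @return named vector of per-parameter ranges of relative errors; attribute
#'   `errors` holds the full n_reps x 4 matrix.
#' @export
perturbation_range <- function(params_ls, spikes, noise_rel_sd = 0.01,
                               n_reps = 15, seed = NULL, weights = NULL) {
  if (inherits(params_ls, "lsf_result")) params_ls <- params_ls$params_ls
  stopifnot(n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  spikes <- as_spike_train(spikes)
  theta <- as.numeric(params_ls)
  M <- length(spikes$times)
  if (is.null(weights)) weights <- rep(1, M)
  avg <- ls_mean(theta, spikes)
  errs <- matrix(NA_real_, n_reps, 4, dimnames = list(NULL, ls_theta_names))
  for (r in seq_len(n_reps)) {
    noisy <- avg * (1 + stats::rnorm(M, 0, noise_rel_sd))
    fit <- lsf_fit(noisy, weights, spikes, init = theta, n_starts = 3)
    errs[r, ] <- (fit$params_ls - theta) / theta
  }
  rng <- apply(errs, 2, function(col) diff(range(col)))
  attr(rng, "errors") <- errs
  rng
}
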