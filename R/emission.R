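# Quantal emission model: the response to m >= 1 released vesicles is
# inverse-Gaussian with mean m*q and variance m*sigma_q^2 (linear summation of
# single-vesicle responses; sums of IGs with a common lambda/mu^2 ratio are
# again IG), optionally convolved with Gaussian baseline noise of SD sigma_n.
# No installed package provides the IG distribution, so it lives here.

#' Inverse-Gaussian quantal density
#'
#' Density of the summed response to `m` vesicles with quantal size `q` and
#' quantal SD `sigma_q` (mean `m q`, variance `m sigma_q^2`), i.e. an inverse
#' Gaussian with mean `m q` and shape `m^2 q^3 / sigma_q^2`.
#'
#' @param x amplitudes, mV (density is 0 for `x <= 0`).  Vectorized.
#' @param m number of vesicles (>= 1).
#' @param q quantal size, mV.
#' @param sigma_q quantal SD, mV (> 0).
#' @param log logical; return log-density.
#' @return density per mV (or its log).
#' @export
dinvgauss_quantal <- function(x, m, q, sigma_q, log = FALSE) {
  stopifnot(m >= 1, q > 0, sigma_q > 0)
  out <- rep(if (log) -Inf else 0, length(x))
  ok <- is.finite(x) & x > 0
  if (any(ok)) {
    y <- x[ok]
    lg <- 0.5 * (2 * log(m) + 3 * log(q) - log(2 * pi * sigma_q^2)) -
      1.5 * log(y) - q * (y - m * q)^2 / (2 * sigma_q^2 * y)
    out[ok] <- if (log) lg else exp(lg)
  }
  out
}

#' Sample quantal responses
#'
#' Draws from the inverse-Gaussian response distribution to `m` vesicles using
#' the standard transformation method (chi-square transform plus a uniform
#' acceptance branch; no unbounded rejection loops).
#'
#' @param n number of draws.
#' @inheritParams dinvgauss_quantal
#' @return numeric vector of amplitudes, mV.
#' @export
rinvgauss_quantal <- function(n, m, q, sigma_q) {
  stopifnot(m >= 1, q > 0, sigma_q > 0)
  mu <- m * q
  lambda <- m^2 * q^3 / sigma_q^2
  nu <- stats::rnorm(n)^2
  x <- mu + mu^2 * nu / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * nu + mu^2 * nu^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Emission density of a postsynaptic response
#'
#' Density of observing amplitude `R` when `m = s_minus - s_plus` vesicles are
#' released.  With baseline noise (`sigma_n > 0`) and `m >= 1` this is the
#' convolution of the inverse-Gaussian quantal density with a centred Gaussian,
#' evaluated by adaptive quadrature; with `m = 0` it is the pure Gaussian
#' baseline density; with `sigma_n = 0` it is the inverse-Gaussian density
#' itself (point evaluation).  The `sigma_n = 0`, `m = 0` case is a point mass
#' at 0 and is only meaningful inside the zero-noise simulation path; it is
#' reported as 1 for `R == 0` and 0 otherwise, and is unusable for inference.
#'
#' This function is the package's reference (adaptive-quadrature) emission; the
#' likelihood engine uses an equivalent fixed Gauss-Legendre rule internally.
#'
#' @param R observed amplitude(s), mV.
#' @param s_minus,s_plus release-competent site counts before/after the spike
#'   (`s_plus <= s_minus`); the number of released vesicles is their
#'   difference.
#' @param q,sigma_q quantal size and SD, mV.
#' @param sigma_n baseline noise SD, mV.
#' @return density per mV, vectorized over `R`.
#' @examples
#' emission_density(0.15, 1, 0, q = 0.15, sigma_q = 0.03, sigma_n = 0)
#' @export
emission_density <- function(R, s_minus, s_plus, q, sigma_q, sigma_n) {
  if (s_plus > s_minus) stop("'s_plus' must not exceed 's_minus'")
  m <- s_minus - s_plus
  if (m == 0) {
    if (sigma_n == 0) return(as.numeric(abs(R) < 1e-12))
    return(stats::dnorm(R, 0, sigma_n))
  }
  sigma_q <- max(sigma_q, 1e-12)
  if (sigma_n == 0) return(dinvgauss_quantal(R, m, q, sigma_q))
  vapply(R, function(r) {
    f <- function(y) dinvgauss_quantal(y, m, q, sigma_q) *
      stats::dnorm(r - y, 0, sigma_n)
    # segment the axis at the critical scales of both factors so the adaptive
    # rule cannot step over a narrow spike (IG bulk or Gaussian window)
    s_ig <- sqrt(m) * sigma_q
    lo <- max(0, min(m * q - 12 * s_ig, r - 12 * sigma_n))
    hi <- max(m * q + 16 * s_ig, r + 12 * sigma_n)
    brk <- sort(unique(pmin(pmax(
      c(lo, r - 12 * sigma_n, r - 2 * sigma_n, r, r + 2 * sigma_n,
        r + 12 * sigma_n, m * q - 10 * s_ig, m * q - 2 * s_ig, m * q,
        m * q + 2 * s_ig, m * q + 12 * s_ig, hi), lo), hi)))
    brk <- brk[c(TRUE, diff(brk) > 1e-14)]
    v <- 0
    for (i in seq_len(length(brk) - 1)) {
      seg <- tryCatch(
        stats::integrate(f, brk[i], brk[i + 1], rel.tol = 1e-10,
                         abs.tol = 1e-300, stop.on.error = FALSE)$value,
        error = function(e) 0)
      v <- v + seg
    }
    v
  }, numeric(1))
}

# Gauss-Legendre rule on [-1, 1] via the Golub-Welsch eigenproblem.
gauss_legendre_rule <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (2 * e$vectors[1, ]^2)[ord])
}

# cached default rule used by the likelihood engine
the_gl_cache <- new.env(parent = emptyenv())
default_gl_rule <- function(n = 60L) {
  key <- as.character(n)
  if (is.null(the_gl_cache[[key]])) the_gl_cache[[key]] <- gauss_legendre_rule(n)
  the_gl_cache[[key]]
}
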