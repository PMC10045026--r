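# Harmonic (trigonometric least-squares) interpolation of the inlet
# waveform, used to turn sampled velocities into a continuous T-periodic
# inlet boundary condition.

#' Fourier series representation of a periodic waveform
#'
#' `u(t) = a0 + sum_k a_k cos(2 pi k t / T) + b_k sin(2 pi k t / T)`.
#'
#' @param period T, s.
#' @param a0 mean term.
#' @param a,b cosine / sine coefficients for harmonics 1..N.
#' @param r_squared optional goodness of fit carried from [fit_fourier()].
#' @return object of class `fourier_series`.
#' @export
fourier_series <- function(period, a0, a, b, r_squared = NA_real_) {
  check_scalar(period, "period", positive = TRUE)
  stop_if_not(length(a) == length(b) && length(a) >= 1,
              "need >= 1 harmonic with matching a/b lengths")
  structure(list(period = period, a0 = a0, a = a, b = b,
                 n_modes = length(a), r_squared = r_squared),
            class = "fourier_series")
}

#' @export
print.fourier_series <- function(x, ...) {
  cat(sprintf("fourier_series: T = %g s, %d modes, a0 = %.4g (R^2 = %.6g)\n",
              x$period, x$n_modes, x$a0, x$r_squared))
  invisible(x)
}

#' Fit a truncated Fourier series to a sampled waveform
#'
#' Least-squares trigonometric regression at multiples of the fundamental
#' frequency `1/T`. On a uniform sample grid this coincides with the
#' discrete Fourier transform of the samples; unlike a raw FFT it also
#' tolerates non-uniform sampling. The goodness of fit is reported as
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param waveform a [sampled_waveform()].
#' @param n_modes number of harmonics N (>= 1); the fit has `2N + 1`
#'   parameters and requires at least that many samples.
#' @return a [fourier_series()] with the fitted coefficients and
#'   `r_squared`; the fitted sample values are attached as attribute
#'   `"fitted"`.
#' @examples
#' wf <- gen_inlet_waveform()
#' fit <- fit_fourier(wf, n_modes = 8)
#' fit$r_squared
#' @export
fit_fourier <- function(waveform, n_modes = 8L) {
  stop_if_not(inherits(waveform, "sampled_waveform"),
              "'waveform' must be a sampled_waveform")
  check_scalar(n_modes, "n_modes", positive = TRUE, integer = TRUE)
  n <- length(waveform$times)
  if (2 * n_modes + 1 > n)
    stop(sprintf("over-parameterized fit: %d parameters for %d samples",
                 2 * n_modes + 1, n), call. = FALSE)
  X <- fourier_design(waveform$times, waveform$period, n_modes)
  fit <- stats::lm.fit(X, waveform$values)
  beta <- unname(fit$coefficients)
  beta[is.na(beta)] <- 0
  fitted <- drop(X %*% beta)
  ss_res <- sum((waveform$values - fitted)^2)
  ss_tot <- sum((waveform$values - mean(waveform$values))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  out <- fourier_series(waveform$period, beta[1],
                        beta[1 + seq_len(n_modes)],
                        beta[1 + n_modes + seq_len(n_modes)],
                        r_squared = r2)
  attr(out, "fitted") <- fitted
  out
}

# design matrix [1 | cos(k w t) | sin(k w t)], k = 1..n_modes
fourier_design <- function(times, period, n_modes) {
  w <- 2 * pi / period
  k <- seq_len(n_modes)
  cbind(1, cos(outer(times, k * w)), sin(outer(times, k * w)))
}

#' Evaluate a Fourier series
#'
#' Exactly T-periodic: `eval_fourier(s, t + T)` equals `eval_fourier(s, t)`
#' up to floating point in the angle reduction.
#'
#' @param series a [fourier_series()].
#' @param t times, s (vectorized).
#' @return waveform values at `t`.
#' @export
eval_fourier <- function(series, t) {
  stop_if_not(inherits(series, "fourier_series"),
              "'series' must be a fourier_series")
  # reduce to [0, T) so distant times do not lose periodicity to round-off
  tr <- t %% series$period
  w <- 2 * pi / series$period
  k <- seq_len(series$n_modes)
  ang <- outer(tr, k * w)
  drop(series$a0 + cos(ang) %*% series$a + sin(ang) %*% series$b)
}
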