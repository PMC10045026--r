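# Physiologic inlet waveform and outlet flow-rate series generators.

#' Sampled periodic waveform
#'
#' Uniformly sampled values of one period of a T-periodic signal, on the
#' grid `t_l = (l - 1) T / n`.
#'
#' @param times strictly increasing sample times in `[0, T)`, s.
#' @param values sample values (m/s for velocity waveforms, m^3/s for flow
#'   series; see `unit`).
#' @param period T, s (> 0).
#' @param unit free-text unit label.
#' @return object of class `sampled_waveform`.
#' @export
sampled_waveform <- function(times, values, period, unit = "m/s") {
  check_scalar(period, "period", positive = TRUE)
  stop_if_not(length(times) == length(values) && length(times) >= 4L,
              "need >= 4 equal-length samples")
  stop_if_not(all(diff(times) > 0) && times[1] >= 0 &&
                times[length(times)] < period,
              "'times' must be strictly increasing within [0, T)")
  stop_if_not(all(is.finite(values)), "non-finite values")
  structure(list(times = times, values = values, period = period,
                 unit = unit),
            class = "sampled_waveform")
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat(sprintf(
    "sampled_waveform: %d samples over T = %g s [%s]; mean %.4g, range [%.4g, %.4g]\n",
    length(x$times), x$period, x$unit, mean(x$values), min(x$values),
    max(x$values)))
  invisible(x)
}

# Raised-cosine bump of unit height centered at phase `c` with full width
# `w` (phases in [0, 1), wrapped periodically); C1-smooth.
.rc_bump <- function(theta, center, width) {
  d <- (theta - center) %% 1
  d[d > 0.5] <- d[d > 0.5] - 1
  out <- numeric(length(theta))
  in_sup <- abs(d) < width / 2
  out[in_sup] <- cos(pi * d[in_sup] / width)^2
  out
}

#' Generate a physiologic inlet velocity waveform
#'
#' Synthesizes one period of an aortic-root velocity waveform from a
#' smooth low-order template (a systolic raised-cosine pulse at phase 0.16
#' of the cycle, plus an early-diastolic backflow notch at phase 0.45) and
#' rescales it so the sampled peak and time-mean match the requested
#' values exactly. When `backflow_depth > 0`, the notch amplitude is
#' solved in closed form so the deepest sample equals `-backflow_depth`,
#' emulating the diastolic backflow seen at the ascending aorta root.
#'
#' Defaults reflect a resting adult aorta: period 0.96 s, systolic peak
#' 0.5 m/s, mean velocity 0.104 m/s (about 6 L/min through a 3.5 cm
#' diameter inlet), and a 0.05 m/s backflow phase.
#'
#' @param period cycle duration T, s.
#' @param peak peak systolic velocity, m/s.
#' @param mean_velocity cycle-mean velocity, m/s; must satisfy
#'   `0 < mean_velocity < peak`.
#' @param backflow_depth magnitude of the most negative sample, m/s
#'   (0 disables backflow, and all samples are then >= 0).
#' @param n_samples samples per period.
#' @param noise_sd optional additive Gaussian noise, m/s (applied after
#'   the constraints are imposed; default 0).
#' @param seed integer seed for the noise.
#' @return a [sampled_waveform()].
#' @examples
#' wf <- gen_inlet_waveform()
#' max(wf$values)   # 0.5
#' mean(wf$values)  # 0.104
#' @export
gen_inlet_waveform <- function(period = 0.96, peak = 0.5,
                               mean_velocity = 0.104, backflow_depth = 0.05,
                               n_samples = 64L, noise_sd = 0, seed = 0L) {
  check_scalar(period, "period", positive = TRUE)
  check_scalar(peak, "peak", positive = TRUE)
  check_scalar(mean_velocity, "mean_velocity", positive = TRUE)
  check_scalar(backflow_depth, "backflow_depth", nonneg = TRUE)
  stop_if_not(mean_velocity < peak,
              "need 0 < mean_velocity < peak")
  stop_if_not(n_samples >= 8, "need at least 8 samples")
  theta <- (seq_len(n_samples) - 1) / n_samples
  sys <- .rc_bump(theta, 0.16, 0.38)
  notch <- .rc_bump(theta, 0.45, 0.20)
  m1 <- mean(sys); m2 <- mean(notch)
  smax <- max(sys)    # ~1, up to sampling of the bump apex
  nmax <- max(notch)  # sampled notch depth scale
  P <- peak; M <- mean_velocity
  if (backflow_depth > 0) {
    # solve the notch amplitude so that, after the exact affine rescale
    # below, the deepest sample sits at -backflow_depth
    depth <- backflow_depth
    num <- (M + depth) * (smax - m1) - (P - M) * m1
    den <- (P - M) * (nmax - m2) - (M + depth) * m2
    d_rel <- num / den
    if (!is.finite(d_rel) || d_rel <= 0 || den <= 0)
      stop("infeasible constraint combination (peak/mean/backflow)",
           call. = FALSE)
  } else {
    d_rel <- 0
  }
  s <- sys - d_rel * notch
  b <- (P - M) / (max(s) - mean(s))
  a <- M - b * mean(s)
  u <- a + b * s
  if (backflow_depth == 0 && min(u) < 0)
    stop("infeasible constraint combination: mean too low for a non-negative waveform",
         call. = FALSE)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    u <- u + stats::rnorm(n_samples, 0, noise_sd)
  }
  sampled_waveform(theta * period, u, period, unit = "m/s")
}

#' Generate an outlet volume-flow series
#'
#' Deterministic periodic flow-rate series used to exercise the Windkessel
#' outflow model. Shapes:
#' \describe{
#'   \item{`constant`}{`Q(t) = level`.}
#'   \item{`half_sine`}{a systolic half-sine pulse of the given `amplitude`
#'     over the first `systole_fraction` of the cycle, zero in diastole,
#'     plus `level`; the pulse integral per cycle is
#'     `amplitude * systole_fraction * period * 2 / pi`.}
#' }
#'
#' @param shape `"constant"` or `"half_sine"`.
#' @param level baseline flow, m^3/s.
#' @param amplitude pulse amplitude, m^3/s (half_sine).
#' @param systole_fraction fraction of the cycle occupied by the pulse.
#' @param period cycle duration, s.
#' @param n_samples samples per period (>= 2).
#' @param noise_sd optional additive Gaussian noise, m^3/s.
#' @param seed integer seed for the noise.
#' @return a [sampled_waveform()] with unit `m^3/s`.
#' @export
gen_outlet_flow <- function(shape = c("half_sine", "constant"),
                            level = 0, amplitude = 1e-4,
                            systole_fraction = 0.35, period = 0.96,
                            n_samples = 64L, noise_sd = 0, seed = 0L) {
  shape <- match.arg(shape)
  check_scalar(period, "period", positive = TRUE)
  stop_if_not(n_samples >= 2, "n_samples < 2")
  n_samples <- max(n_samples, 4L)  # container minimum
  theta <- (seq_len(n_samples) - 1) / n_samples
  q <- switch(shape,
    constant = rep(level, n_samples),
    half_sine = {
      stop_if_not(systole_fraction > 0 && systole_fraction <= 1,
                  "'systole_fraction' must be in (0, 1]")
      pulse <- ifelse(theta < systole_fraction,
                      sin(pi * theta / systole_fraction), 0)
      level + amplitude * pulse
    })
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    q <- q + stats::rnorm(n_samples, 0, noise_sd)
  }
  sampled_waveform(theta * period, q, period, unit = "m^3/s")
}
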