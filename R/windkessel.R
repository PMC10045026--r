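# Three-element Windkessel outflow model: explicit-Euler time integration
# and parameter estimation from a target mean pressure.

#' Three-element Windkessel parameters
#'
#' Lumped model of the vascular bed downstream of an outlet: proximal
#' resistance `R1` in series with the parallel pair of distal resistance
#' `R2` and compliance `C`. The steady-state (DC) relation is
#' `p = (R1 + R2) Q`.
#'
#' @param R1 proximal resistance, Pa s/m^3 (> 0).
#' @param R2 distal resistance, Pa s/m^3 (> 0).
#' @param C compliance, m^3/Pa (> 0).
#' @return object of class `windkessel_params`.
#' @export
windkessel_params <- function(R1, R2, C) {
  check_scalar(R1, "R1", positive = TRUE)
  check_scalar(R2, "R2", positive = TRUE)
  check_scalar(C, "C", positive = TRUE)
  structure(list(R1 = R1, R2 = R2, C = C), class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf("windkessel: R1 = %.4g, R2 = %.4g Pa s/m^3, C = %.4g m^3/Pa (tau = %.4g s)\n",
              x$R1, x$R2, x$C, x$R2 * x$C))
  invisible(x)
}

#' Integrate the 3-element Windkessel in time (explicit Euler)
#'
#' The model is integrated in the distal pressure variable
#' `p2 = p - R1 Q`, which satisfies
#' \deqn{\frac{dp_2}{dt} = \frac{Q}{C} - \frac{p_2}{R_2 C},}
#' with explicit Euler stepping, and the outlet pressure recovered as
#' `p = p2 + R1 Q`. This is the standard RCR circuit whose steady state is
#' `p = (R1 + R2) Q`. Explicit Euler is conditionally stable: `dt` must be
#' below `2 R2 C` or the step is rejected (and below `R2 C` for the
#' discrete solution to stay sign-preserving).
#'
#' `p_initial` initializes the ODE state `p2` — the compliance (distal)
#' pressure — so a zero-flow run decays as `p(t) = p_initial
#' exp(-t/(R2 C))`, and starting from rest (`p_initial = 0`) with
#' non-negative flow keeps the outlet pressure non-negative (passivity)
#' whenever `dt <= R2 C`.
#'
#' @param params a [windkessel_params()].
#' @param Q flow-rate samples over one period, m^3/s (a numeric vector or
#'   a [sampled_waveform()]); treated as periodic and repeated for
#'   `n_cycles` cycles.
#' @param dt time step, s; defaults to `period / 1000` when `Q` is a
#'   sampled_waveform (whose samples are then linearly interpolated onto
#'   the integration grid), else to the sample spacing.
#' @param p_initial initial distal (compliance) pressure `p2(0)`, Pa.
#' @param n_cycles number of cycles to integrate.
#' @param period cycle duration, s (required when `Q` is a plain vector).
#' @return object of class `outlet_series`: list with `times`, `Q`, `p`
#'   (Pa), `dt`, `period`, `n_cycles`.
#' @examples
#' wk <- windkessel_params(1.2e7, 1.08e8, 1e-9)
#' qs <- gen_outlet_flow("half_sine", amplitude = 3e-4)
#' out <- wk3_integrate(wk, qs, n_cycles = 4)
#' mean(out$p[out$times >= 3 * out$period])
#' @export
wk3_integrate <- function(params, Q, dt = NULL, p_initial = 0,
                          n_cycles = 1L, period = NULL) {
  stop_if_not(inherits(params, "windkessel_params"),
              "'params' must be windkessel_params")
  check_scalar(n_cycles, "n_cycles", positive = TRUE, integer = TRUE)
  if (inherits(Q, "sampled_waveform")) {
    period <- Q$period
    if (is.null(dt)) dt <- period / 1000
    nsteps <- round(period / dt)
    stop_if_not(abs(nsteps * dt - period) < 1e-9 * period,
                "'dt' must divide the period")
    tgrid <- (seq_len(nsteps) - 1) * dt
    # periodic linear interpolation of the samples onto the Euler grid
    tt <- c(Q$times, Q$times[1] + period)
    vv <- c(Q$values, Q$values[1])
    qcycle <- stats::approx(tt, vv, xout = tgrid, rule = 2)$y
  } else {
    stop_if_not(is.numeric(Q) && length(Q) >= 2, "'Q' must have >= 2 samples")
    if (is.null(period) && is.null(dt))
      stop("supply 'period' or 'dt' with a plain Q vector", call. = FALSE)
    if (is.null(dt)) dt <- period / length(Q)
    if (is.null(period)) period <- dt * length(Q)
    qcycle <- Q
    nsteps <- length(Q)
  }
  check_scalar(dt, "dt", positive = TRUE)
  tau <- params$R2 * params$C
  if (dt >= 2 * tau)
    stop(sprintf(
      "explicit Euler unstable: dt = %g exceeds the stability bound 2 R2 C = %g",
      dt, 2 * tau), call. = FALSE)
  q <- rep(qcycle, n_cycles)
  n <- length(q)
  p2 <- numeric(n)
  p2[1] <- p_initial
  for (l in seq_len(n - 1)) {
    p2[l + 1] <- p2[l] + dt * (q[l] / params$C - p2[l] / tau)
  }
  p <- p2 + params$R1 * q
  structure(list(times = (seq_len(n) - 1) * dt, Q = q, p = p, dt = dt,
                 period = period, n_cycles = n_cycles, params = params),
            class = "outlet_series")
}

#' @export
print.outlet_series <- function(x, ...) {
  cat(sprintf("outlet_series: %d cycles of T = %g s at dt = %g s; final-cycle mean p = %.4g Pa\n",
              x$n_cycles, x$period, x$dt,
              mean(x$p[x$times >= (x$n_cycles - 1) * x$period])))
  invisible(x)
}

#' Estimate Windkessel constants from a target mean pressure
#'
#' Splits the total resistance `RT = target_mean_pressure / mean(Q)` into
#' a proximal fraction `R1 = r1_fraction * RT` and distal remainder
#' `R2 = RT - R1`, and sets the compliance from a prescribed exponential
#' time constant: `C = time_constant_fraction * period / R2`. Re-simulating
#' the same periodic flow with the estimated constants reproduces the
#' target cycle-mean pressure (within the Euler discretization error).
#'
#' @param target_mean_pressure desired cycle-mean outlet pressure, Pa.
#' @param Q periodic flow-rate samples (vector or [sampled_waveform()])
#'   with positive mean.
#' @param period cycle duration, s (taken from `Q` when it is a
#'   sampled_waveform).
#' @param r1_fraction proximal share of the total resistance, in (0, 1);
#'   default 0.1.
#' @param time_constant_fraction `R2 C` as a fraction of the period;
#'   default 0.35.
#' @return a [windkessel_params()].
#' @examples
#' wk3_estimate(1.2e4, rep(1e-4, 32), period = 0.96, r1_fraction = 0.1)
#' @export
wk3_estimate <- function(target_mean_pressure, Q, period = NULL,
                         r1_fraction = 0.1, time_constant_fraction = 0.35) {
  check_scalar(target_mean_pressure, "target_mean_pressure", positive = TRUE)
  stop_if_not(r1_fraction > 0 && r1_fraction < 1,
              "'r1_fraction' must be in (0, 1)")
  check_scalar(time_constant_fraction, "time_constant_fraction",
               positive = TRUE)
  if (inherits(Q, "sampled_waveform")) {
    period <- Q$period
    qbar <- mean(Q$values)
  } else {
    qbar <- mean(Q)
  }
  check_scalar(period, "period", positive = TRUE)
  if (qbar <= 0)
    stop("non-positive mean flow: cannot estimate resistances", call. = FALSE)
  RT <- target_mean_pressure / qbar
  R1 <- r1_fraction * RT
  R2 <- RT - R1
  C <- time_constant_fraction * period / R2
  windkessel_params(R1, R2, C)
}
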