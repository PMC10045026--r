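# Analytic flow fields with closed-form velocity, velocity gradient and
# wall shear: Poiseuille and Womersley pipe flow, rigid rotation, and pure
# shear. These are the oracles for the wall-shear and vortex operators.

# --- complex-argument Bessel functions --------------------------------
# J0 and J1 for complex z. Small arguments (|z| <= 14) use the power
# series with a term recurrence (cancellation error there stays below
# ~1e-8); larger arguments use the 3-term Hankel asymptotic expansion
# (A&S 9.2.5-9.2.10), accurate to better than 1e-6 beyond the switch
# point. This covers the full Womersley-number range of aortic flow
# (alpha up to several hundred before exp overflow).
.besselJ0_c <- function(z) {
  if (Mod(z) <= 14) {
    term <- 1 + 0i
    s <- term
    q <- -z * z / 4
    for (k in 1:200) {
      term <- term * q / (k * k)
      s <- s + term
      if (Mod(term) < 1e-18 * max(Mod(s), 1e-300)) break
    }
    s
  } else {
    P <- 1 - 9 / (128 * z^2) + 11025 / (98304 * z^4)
    Q <- -1 / (8 * z) + 75 / (1024 * z^3)
    chi <- z - pi / 4
    sqrt(2 / (pi * z)) * (P * cos(chi) - Q * sin(chi))
  }
}

.besselJ1_c <- function(z) {
  if (Mod(z) <= 14) {
    term <- 1 + 0i
    s <- term
    q <- -z * z / 4
    for (k in 1:200) {
      term <- term * q / (k * (k + 1))
      s <- s + term
      if (Mod(term) < 1e-18 * max(Mod(s), 1e-300)) break
    }
    s * z / 2
  } else {
    P <- 1 + 15 / (128 * z^2) - 14175 / (98304 * z^4)
    Q <- 3 / (8 * z) - 105 / (1024 * z^3)
    chi <- z - 3 * pi / 4
    sqrt(2 / (pi * z)) * (P * cos(chi) - Q * sin(chi))
  }
}

#' Specification of an analytic flow field
#'
#' Describes one of four closed-form fields:
#' \describe{
#'   \item{`poiseuille`}{steady axisymmetric pipe flow,
#'     `u_z(r) = 2 u_mean (1 - r^2/R^2)`, axis along z.}
#'   \item{`womersley`}{pulsatile pipe flow driven by a harmonic axial
#'     pressure gradient `-dp/dz = sum_n G_n cos(w_n t + phi_n)`; each
#'     harmonic contributes the classical Bessel-function profile. A
#'     zero-frequency harmonic contributes its steady Poiseuille limit.}
#'   \item{`rigid_rotation`}{solid-body rotation `u = omega x r` about the
#'     z axis at `rate` rad/s.}
#'   \item{`pure_shear`}{simple shear `u_x = gamma y`.}
#' }
#'
#' @param kind one of `"poiseuille"`, `"womersley"`, `"rigid_rotation"`,
#'   `"pure_shear"`.
#' @param radius pipe radius R in m (pipe kinds).
#' @param u_mean mean axial velocity, m/s (poiseuille).
#' @param harmonics data.frame with columns `amplitude` (pressure-gradient
#'   magnitude, Pa/m), `phase` (rad) and `frequency` (Hz); womersley only.
#' @param rate rotation rate, rad/s (rigid_rotation).
#' @param gamma shear rate, 1/s (pure_shear).
#' @param fluid a [fluid_properties()].
#' @param n_radial,n_theta,n_axial cylindrical sampling counts (pipe kinds).
#' @param n_time number of snapshot times over one period (>= 2 for
#'   unsteady kinds; steady kinds default to a single snapshot).
#' @param axial_length sampled pipe length, m.
#' @param near_wall_distance wall distance d of the paired near-wall
#'   samples, m; default `radius / 200`.
#' @param seed integer seed (kept for interface uniformity; the generators
#'   are deterministic).
#' @return object of class `analytic_field_spec`.
#' @seealso [gen_analytic_field()]
#' @export
analytic_field_spec <- function(kind = c("poiseuille", "womersley",
                                         "rigid_rotation", "pure_shear"),
                                radius = 0.0175, u_mean = 0.25,
                                harmonics = NULL, rate = 1, gamma = 1,
                                fluid = fluid_properties(),
                                n_radial = 24L, n_theta = 16L, n_axial = 4L,
                                n_time = NULL, axial_length = 0.02,
                                near_wall_distance = NULL, seed = 0L) {
  kind <- match.arg(kind)
  check_scalar(radius, "radius", positive = TRUE)
  if (kind == "womersley") {
    stop_if_not(is.data.frame(harmonics) &&
                  all(c("amplitude", "phase", "frequency") %in%
                        names(harmonics)) && nrow(harmonics) >= 1,
                "womersley needs a harmonics data.frame (amplitude, phase, frequency)")
    stop_if_not(all(harmonics$frequency >= 0), "frequencies must be >= 0")
    if (is.null(n_time)) n_time <- 32L
    if (any(harmonics$frequency > 0))
      stop_if_not(n_time >= 2, "n_time >= 2 required for unsteady fields")
  }
  if (is.null(n_time)) n_time <- 1L
  if (is.null(near_wall_distance)) near_wall_distance <- radius / 200
  stop_if_not(near_wall_distance > 0 && near_wall_distance < radius,
              "near_wall_distance must lie in (0, radius)")
  structure(list(kind = kind, radius = radius, u_mean = u_mean,
                 harmonics = harmonics, rate = rate, gamma = gamma,
                 fluid = fluid, n_radial = as.integer(n_radial),
                 n_theta = as.integer(n_theta), n_axial = as.integer(n_axial),
                 n_time = as.integer(n_time), axial_length = axial_length,
                 near_wall_distance = near_wall_distance,
                 seed = as.integer(seed)),
            class = "analytic_field_spec")
}

# Womersley radial profile helpers. Return complex amplitude fields such
# that u(r, t) = sum_n Re(amp_n(r) * exp(i w_n t)).
.womersley_terms <- function(harmonics, R, fluid) {
  lapply(seq_len(nrow(harmonics)), function(n) {
    G <- harmonics$amplitude[n]
    phi <- harmonics$phase[n]
    f <- harmonics$frequency[n]
    if (f == 0) {
      # steady limit: Poiseuille under gradient G cos(phi)
      list(steady = TRUE, G = G * cos(phi))
    } else {
      w <- 2 * pi * f
      alpha <- R * sqrt(w / fluid$nu)
      Lam <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^{3/2} alpha
      list(steady = FALSE, w = w, C = G * exp(1i * phi) / (1i * fluid$rho * w),
           Lam = Lam, J0L = .besselJ0_c(Lam))
    }
  })
}

# axial velocity u_z(r, t) for a womersley term list
.womersley_uz <- function(terms, r, t, R, fluid) {
  u <- numeric(length(r))
  for (tm in terms) {
    if (tm$steady) {
      u <- u + tm$G / (4 * fluid$mu) * (R^2 - r^2)
    } else {
      prof <- 1 - vapply(r, function(ri) .besselJ0_c(tm$Lam * ri / R),
                         complex(1)) / tm$J0L
      u <- u + Re(tm$C * prof * exp(1i * tm$w * t))
    }
  }
  u
}

# radial derivative du_z/dr (r, t)
.womersley_dudr <- function(terms, r, t, R, fluid) {
  g <- numeric(length(r))
  for (tm in terms) {
    if (tm$steady) {
      g <- g - tm$G * r / (2 * fluid$mu)
    } else {
      j1 <- vapply(r, function(ri) .besselJ1_c(tm$Lam * ri / R), complex(1))
      g <- g + Re(tm$C * (tm$Lam / R) * j1 / tm$J0L * exp(1i * tm$w * t))
    }
  }
  g
}

#' Generate an analytic flow field with closed-form references
#'
#' Builds time snapshots of the field described by an
#' [analytic_field_spec()], together with (for pipe kinds) a [wall_patch()]
#' whose near-wall samples sit at distance `d` inside the fluid, and a
#' `reference` list of closed-form callbacks:
#' \describe{
#'   \item{`velocity(points, t)`}{exact velocity vectors at arbitrary
#'     points.}
#'   \item{`gradient(points, t)`}{exact 3 x 3 velocity-gradient tensors
#'     (array `3 x 3 x n`, entry `[i, j, ]` is `du_i/dx_j`).}
#'   \item{`wall_shear(t)`}{exact per-face WSS vectors at time t (pipe
#'     kinds), and `wall_shear_scalar(t)`, the signed axial component
#'     common to all faces.}
#' }
#'
#' Pipe snapshots sample annulus midpoints `r_j = (j - 1/2) R / n_radial`
#' over `n_theta` azimuths and `n_axial` axial stations, append the
#' near-wall ring points (indexed by `patch$near_index`), and attach
#' cross-section area weights for backflow-fraction diagnostics. Rotation
#' and shear fields are returned as cubic-lattice snapshots suitable for
#' [velocity_gradient()].
#'
#' @param spec an [analytic_field_spec()].
#' @return object of class `analytic_field`: list with `kind`, `times`,
#'   `snapshots`, `patch` (pipe kinds, else NULL), `reference`, `period`
#'   (womersley, else NULL) and the originating `spec`.
#' @examples
#' fld <- gen_analytic_field(analytic_field_spec("poiseuille"))
#' fld$reference$wall_shear_scalar(0)  # 4 mu u_mean / R
#' @export
gen_analytic_field <- function(spec) {
  stop_if_not(inherits(spec, "analytic_field_spec"),
              "'spec' must be an analytic_field_spec")
  fluid <- spec$fluid
  R <- spec$radius
  switch(spec$kind,
    poiseuille = .gen_pipe_field(spec, steady = TRUE),
    womersley = .gen_pipe_field(spec, steady = FALSE),
    rigid_rotation = .gen_lattice_field(spec,
      velocity = function(p, t) cbind(-spec$rate * p[, 2L],
                                      spec$rate * p[, 1L],
                                      rep(0, nrow(p))),
      gradient = function(p, t) {
        g <- array(0, c(3, 3, nrow(p)))
        g[1, 2, ] <- -spec$rate
        g[2, 1, ] <- spec$rate
        g
      }),
    pure_shear = .gen_lattice_field(spec,
      velocity = function(p, t) cbind(spec$gamma * p[, 2L],
                                      rep(0, nrow(p)), rep(0, nrow(p))),
      gradient = function(p, t) {
        g <- array(0, c(3, 3, nrow(p)))
        g[1, 2, ] <- spec$gamma
        g
      })
  )
}

# shared machinery for poiseuille / womersley pipe fields
.gen_pipe_field <- function(spec, steady) {
  fluid <- spec$fluid
  R <- spec$radius
  d <- spec$near_wall_distance
  if (steady) {
    umax <- 2 * spec$u_mean
    uz_fun <- function(r, t) umax * (1 - (r / R)^2)
    dudr_fun <- function(r, t) -2 * umax * r / R^2
    period <- NULL
    times <- if (spec$n_time > 1)
      seq(0, 1, length.out = spec$n_time + 1)[1:spec$n_time] else 0
  } else {
    terms <- .womersley_terms(spec$harmonics, R, fluid)
    uz_fun <- function(r, t) .womersley_uz(terms, r, t, R, fluid)
    dudr_fun <- function(r, t) .womersley_dudr(terms, r, t, R, fluid)
    fpos <- spec$harmonics$frequency[spec$harmonics$frequency > 0]
    period <- if (length(fpos)) 1 / min(fpos) else NULL
    times <- if (!is.null(period))
      seq(0, period, length.out = spec$n_time + 1)[1:spec$n_time] else 0
  }
  # cylindrical interior sampling (annulus midpoints) + near-wall ring
  rj <- (seq_len(spec$n_radial) - 0.5) * R / spec$n_radial
  dr <- R / spec$n_radial
  th <- 2 * pi * (seq_len(spec$n_theta) - 1) / spec$n_theta
  zk <- spec$axial_length * (seq_len(spec$n_axial) - 0.5) / spec$n_axial
  grid <- expand.grid(r = rj, theta = th, z = zk)
  interior <- cbind(grid$r * cos(grid$theta), grid$r * sin(grid$theta),
                    grid$z)
  # per-point cross-section area weight, normalized per axial station
  aw <- (2 * pi * grid$r * dr / spec$n_theta) / (pi * R^2) / spec$n_axial
  # wall faces: one per (theta, z)
  wf <- expand.grid(theta = th, z = zk)
  n_faces <- nrow(wf)
  normal <- cbind(cos(wf$theta), sin(wf$theta), rep(0, n_faces))
  wall_point <- cbind(R * cos(wf$theta), R * sin(wf$theta), wf$z)
  near_point <- cbind((R - d) * cos(wf$theta), (R - d) * sin(wf$theta), wf$z)
  area <- rep(2 * pi * R / spec$n_theta * spec$axial_length / spec$n_axial,
              n_faces)
  near_index <- nrow(interior) + seq_len(n_faces)
  patch <- wall_patch(area, normal, wall_point, near_point,
                      rep(d, n_faces), near_index)
  locations <- rbind(interior, near_point)
  rloc <- sqrt(locations[, 1L]^2 + locations[, 2L]^2)
  velocity_fun <- function(points, t) {
    r <- sqrt(points[, 1L]^2 + points[, 2L]^2)
    cbind(0, 0, uz_fun(r, t))
  }
  gradient_fun <- function(points, t) {
    r <- sqrt(points[, 1L]^2 + points[, 2L]^2)
    du <- dudr_fun(r, t)
    g <- array(0, c(3, 3, nrow(points)))
    safe <- r > 1e-14
    gx <- gy <- numeric(nrow(points))
    gx[safe] <- du[safe] * points[safe, 1L] / r[safe]
    gy[safe] <- du[safe] * points[safe, 2L] / r[safe]
    g[3, 1, ] <- gx
    g[3, 2, ] <- gy
    g
  }
  wall_shear_scalar <- function(t) -fluid$mu * dudr_fun(R, t)
  wall_shear <- function(t) {
    s <- wall_shear_scalar(t)
    cbind(0, 0, rep(s, n_faces))
  }
  snapshots <- lapply(times, function(t)
    field_snapshot(time = t, locations = locations,
                   velocity = cbind(0, 0, uz_fun(rloc, t)),
                   area_weight = c(aw, rep(0, n_faces))))
  structure(list(kind = spec$kind, times = times, snapshots = snapshots,
                 patch = patch, period = period,
                 reference = list(velocity = velocity_fun,
                                  gradient = gradient_fun,
                                  wall_shear = wall_shear,
                                  wall_shear_scalar = wall_shear_scalar),
                 spec = spec),
            class = "analytic_field")
}

.gen_lattice_field <- function(spec, velocity, gradient) {
  n <- max(spec$n_radial, 4L)
  # cube of side 2R centered on the origin
  ax <- seq(-spec$radius, spec$radius, length.out = n)
  h <- ax[2] - ax[1]
  grid <- expand.grid(x = ax, y = ax, z = ax)  # x fastest: lattice order
  pts <- as.matrix(grid)
  times <- 0
  snapshots <- list(field_snapshot(
    time = 0, locations = pts, velocity = velocity(pts, 0),
    lattice = list(dims = c(n, n, n), spacing = c(h, h, h),
                   origin = c(ax[1], ax[1], ax[1]))))
  structure(list(kind = spec$kind, times = times, snapshots = snapshots,
                 patch = NULL, period = NULL,
                 reference = list(velocity = velocity, gradient = gradient,
                                  wall_shear = NULL,
                                  wall_shear_scalar = NULL),
                 spec = spec),
            class = "analytic_field")
}

#' Sample a closed-form field on a regular lattice
#'
#' Evaluates an [gen_analytic_field()] reference velocity on a regular
#' lattice and returns a [field_snapshot()] with lattice metadata, ready
#' for finite-difference gradient evaluation.
#'
#' @param field an `analytic_field`.
#' @param n lattice points per axis (scalar or length 3).
#' @param lower,upper corner coordinates of the sampled box, m.
#' @param time evaluation time, s.
#' @return a [field_snapshot()].
#' @export
sample_lattice_snapshot <- function(field, n, lower, upper, time = 0) {
  stop_if_not(inherits(field, "analytic_field"), "need an analytic_field")
  if (length(n) == 1L) n <- rep(n, 3L)
  stop_if_not(all(n >= 2), "need at least 2 lattice points per axis")
  axs <- lapply(1:3, function(i) seq(lower[i], upper[i], length.out = n[i]))
  h <- vapply(axs, function(a) a[2] - a[1], numeric(1))
  grid <- expand.grid(x = axs[[1]], y = axs[[2]], z = axs[[3]])
  pts <- as.matrix(grid)
  field_snapshot(time = time, locations = pts,
                 velocity = field$reference$velocity(pts, time),
                 lattice = list(dims = n, spacing = h,
                                origin = c(lower[1], lower[2], lower[3])))
}
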