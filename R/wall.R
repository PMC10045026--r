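# Wall shear post-processing: WSS from near-wall velocities, wall shear
# force, TAWSS, OSI and y+.

#' Discrete wall patch
#'
#' A set of wall faces with the quantities needed for one-sided wall-shear
#' evaluation: face area, unit outward normal, the wall point, a paired
#' near-wall sample point at distance `d` inside the fluid, and the index
#' of that sample in the companion [field_snapshot()].
#'
#' @param area numeric vector of face areas, m^2 (> 0).
#' @param normal n x 3 matrix of unit outward normals.
#' @param wall_point,near_point n x 3 matrices of coordinates, m.
#' @param distance wall distances of the near points, m (> 0).
#' @param near_index integer index of each face's near-wall sample in the
#'   snapshot's location list (defaults to `1:n`).
#' @return object of class `wall_patch`.
#' @export
wall_patch <- function(area, normal, wall_point, near_point, distance,
                       near_index = seq_along(area)) {
  n <- length(area)
  stop_if_not(all(area > 0), "face areas must be > 0")
  stop_if_not(is.matrix(normal) && nrow(normal) == n && ncol(normal) == 3L,
              "'normal' must be an n x 3 matrix")
  stop_if_not(max(abs(row_norms(normal) - 1)) < 1e-8,
              "normals must be unit length")
  stop_if_not(all(distance > 0), "wall distances must be > 0")
  stop_if_not(length(distance) == n && length(near_index) == n &&
                nrow(wall_point) == n && nrow(near_point) == n,
              "inconsistent face counts")
  structure(list(area = area, normal = normal, wall_point = wall_point,
                 near_point = near_point, distance = distance,
                 near_index = as.integer(near_index), n_faces = n),
            class = "wall_patch")
}

#' Velocity (and optional scalar) field snapshot
#'
#' One time level of a flow solution sampled on points: locations, velocity
#' vectors, and optional pressure and turbulent kinetic energy. For
#' snapshots on a regular lattice, `lattice` carries `dims = c(nx, ny, nz)`,
#' `spacing = c(dx, dy, dz)` and `origin`; points are ordered x-fastest,
#' then y, then z, which is what [velocity_gradient()] requires.
#'
#' @param time snapshot time, s.
#' @param locations n x 3 matrix of sample coordinates, m.
#' @param velocity n x 3 matrix of velocity vectors, m/s.
#' @param pressure optional numeric vector, Pa.
#' @param k optional turbulent kinetic energy vector, m^2/s^2.
#' @param lattice optional lattice metadata (see above).
#' @param area_weight optional per-sample cross-section area weight used by
#'   area-fraction diagnostics.
#' @return object of class `field_snapshot`.
#' @export
field_snapshot <- function(time, locations, velocity, pressure = NULL,
                           k = NULL, lattice = NULL, area_weight = NULL) {
  stop_if_not(is.matrix(locations) && ncol(locations) == 3L,
              "'locations' must be an n x 3 matrix")
  stop_if_not(is.matrix(velocity) && all(dim(velocity) == dim(locations)),
              "'velocity' must match 'locations' in shape")
  stop_if_not(all(is.finite(velocity)), "non-finite velocities")
  if (!is.null(pressure))
    stop_if_not(length(pressure) == nrow(locations), "bad pressure length")
  if (!is.null(k))
    stop_if_not(length(k) == nrow(locations) && all(k >= -1e-300),
                "bad turbulent kinetic energy")
  structure(list(time = time, locations = locations, velocity = velocity,
                 pressure = pressure, k = k, lattice = lattice,
                 area_weight = area_weight),
            class = "field_snapshot")
}

#' Wall shear stress from a snapshot and a wall patch
#'
#' Evaluates the wall traction `-mu * du/dn` at every face with a
#' one-sided first-order difference between the wall (no-slip, zero
#' velocity) and the paired near-wall sample at distance `d`:
#' \deqn{\vec{WSS} = -\mu\,\frac{\vec u_{wall} - \vec u_{near}}{d}
#'                 = \mu\,\vec u_{near} / d.}
#' This mirrors a first-cell-center evaluation in a low-Reynolds wall
#' treatment without wall functions. By default the full vector is
#' reported; `tangential = TRUE` removes the wall-normal component first
#' (tangential traction).
#'
#' @param snapshot a [field_snapshot()].
#' @param patch a [wall_patch()]; `patch$near_index` selects each face's
#'   near-wall velocity sample.
#' @param fluid a [fluid_properties()].
#' @param tangential subtract the wall-normal component (default FALSE).
#' @return n_faces x 3 matrix of WSS vectors, Pa.
#' @export
compute_wss <- function(snapshot, patch, fluid = fluid_properties(),
                        tangential = FALSE) {
  stop_if_not(inherits(snapshot, "field_snapshot"), "need a field_snapshot")
  stop_if_not(inherits(patch, "wall_patch"), "need a wall_patch")
  stop_if_not(all(patch$distance > 0), "wall distance d <= 0")
  stop_if_not(max(patch$near_index) <= nrow(snapshot$velocity),
              "near-wall sample index outside the snapshot")
  u <- snapshot$velocity[patch$near_index, , drop = FALSE]
  wss <- fluid$mu * u / patch$distance
  if (tangential) {
    wn <- rowSums(wss * patch$normal)
    wss <- wss - wn * patch$normal
  }
  wss
}

#' Wall shear force: surface integral of the WSS vector
#'
#' Discrete surface integral `sum(WSS_f * area_f)` over the faces of a
#' wall patch.
#'
#' @param wss n_faces x 3 matrix of WSS vectors, Pa.
#' @param patch a [wall_patch()].
#' @return list with `force` (3-vector, N) and `magnitude` (scalar N, the
#'   WSF value reported by the sensitivity metrics).
#' @export
compute_wsf <- function(wss, patch) {
  stop_if_not(inherits(patch, "wall_patch"), "need a wall_patch")
  stop_if_not(is.matrix(wss) && nrow(wss) == patch$n_faces &&
                ncol(wss) == 3L, "'wss' must be n_faces x 3")
  force <- colSums(wss * patch$area)
  list(force = force, magnitude = sqrt(sum(force^2)))
}

#' One-period wall shear history
#'
#' Stores per-face WSS vectors over one cardiac cycle on a uniform time
#' grid `t_l = (l-1) T / n, l = 1..n` (the endpoint `t = T` is the periodic
#' image of `t = 0` and is not duplicated). On this grid the periodic
#' trapezoidal rule reduces to the plain sample mean, which is what the
#' cycle-average operators use.
#'
#' @param times numeric vector of sample times covering `[0, T)`.
#' @param wss `n_faces x 3 x n_times` array of WSS vectors, Pa.
#' @param period cycle duration T, s.
#' @return object of class `wss_history`.
#' @export
wss_history <- function(times, wss, period) {
  check_scalar(period, "period", positive = TRUE)
  nt <- length(times)
  stop_if_not(nt >= 4L, "need at least 4 time samples")
  stop_if_not(is.array(wss) && length(dim(wss)) == 3L && dim(wss)[2] == 3L &&
                dim(wss)[3] == nt, "'wss' must be n_faces x 3 x n_times")
  stop_if_not(all(is.finite(wss)), "non-finite WSS values")
  dt <- diff(times)
  stop_if_not(max(abs(dt - dt[1])) < 1e-9 * period,
              "time grid must be uniform")
  stop_if_not(abs(times[1]) < 1e-12 &&
                abs(times[nt] + dt[1] - period) < 1e-9 * period,
              "times must cover exactly one period [0, T)")
  structure(list(times = times, wss = wss, period = period,
                 n_faces = dim(wss)[1], n_times = nt),
            class = "wss_history")
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per-face cycle average of the WSS magnitude,
#' `TAWSS = (1/T) integral_0^T |WSS| dt`, evaluated with the periodic
#' trapezoidal rule on the uniform one-period grid (equivalent to the
#' sample mean).
#'
#' @param history a [wss_history()].
#' @return numeric vector of per-face TAWSS, Pa.
#' @export
tawss <- function(history) {
  stop_if_not(inherits(history, "wss_history"), "need a wss_history")
  mags <- sqrt(apply(history$wss^2, c(1, 3), sum))
  if (is.null(dim(mags))) mags <- matrix(mags, history$n_faces)
  rowMeans(mags)
}

#' Oscillatory shear index (OSI)
#'
#' Per-face directional-reversal measure of the WSS over one cycle:
#' \deqn{OSI = \frac12\left(1 -
#'   \frac{\|\frac1T\int_0^T \vec{WSS}\,dt\|}
#'        {\frac1T\int_0^T \|\vec{WSS}\|\,dt}\right),}
#' with both integrals taken by the same periodic trapezoidal rule.
#' OSI is 0 for unidirectional shear and approaches 0.5 when the vector
#' mean vanishes. A face whose WSS history is identically zero is a 0/0
#' case; it is reported as 0 with a warning (a dead face does not
#' oscillate).
#'
#' @param history a [wss_history()].
#' @return numeric vector of per-face OSI in `[0, 0.5]`.
#' @export
osi <- function(history) {
  stop_if_not(inherits(history, "wss_history"), "need a wss_history")
  w <- history$wss
  mean_vec <- apply(w, c(1, 2), mean)            # n_faces x 3
  if (is.null(dim(mean_vec))) mean_vec <- matrix(mean_vec, history$n_faces)
  mean_mag <- tawss(history)
  num <- row_norms(mean_vec)
  out <- numeric(history$n_faces)
  dead <- mean_mag == 0
  if (any(dead))
    warning(sprintf("%d face(s) with identically zero WSS history: OSI set to 0",
                    sum(dead)))
  live <- !dead
  out[live] <- 0.5 * (1 - num[live] / mean_mag[live])
  # guard tiny negative round-off
  pmin(pmax(out, 0), 0.5)
}

#' Non-dimensional wall distance y+
#'
#' `y+ = y * u_tau / nu` with friction velocity `u_tau = sqrt(WSS / rho)`.
#' Values below 5 indicate that the viscous sublayer is resolved by the
#' near-wall discretization.
#'
#' @param wss_mag wall shear stress magnitude, Pa (>= 0).
#' @param y wall distance, m (>= 0).
#' @param fluid a [fluid_properties()].
#' @return dimensionless y+ (vectorized over `wss_mag` / `y`).
#' @examples
#' yplus(1, 2.5e-5)  # about 0.22 for blood
#' @export
yplus <- function(wss_mag, y, fluid = fluid_properties()) {
  stop_if_not(all(wss_mag >= 0) && all(y >= 0), "inputs must be >= 0")
  y * sqrt(wss_mag / fluid$rho) / fluid$nu
}
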