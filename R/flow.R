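# Velocity-gradient tensor, Q-criterion vortex identification, turbulence
# intensity, and axial-velocity / backflow diagnostics.

#' Velocity-gradient tensor field
#'
#' Computes the per-sample 3 x 3 tensors `du_i/dx_j`. Two routes:
#' \itemize{
#'   \item a [field_snapshot()] carrying lattice metadata: central
#'     differences in the interior and one-sided first-order differences at
#'     the lattice boundary (exact for fields linear in the coordinates);
#'   \item an `analytic_field` from [gen_analytic_field()]: the exact
#'     closed-form tensor via the reference callback.
#' }
#' Unstructured snapshots without lattice metadata are rejected: computing
#' gradients there requires solver-grade reconstruction, which is out of
#' scope — resample the field on a lattice instead (see
#' [sample_lattice_snapshot()]).
#'
#' @param x a `field_snapshot` with `lattice` metadata, or an
#'   `analytic_field`.
#' @param points,time evaluation points (n x 3) and time for the analytic
#'   route; defaults to the field's own first snapshot.
#' @return object of class `gradient_field`: list with `tensors`
#'   (`3 x 3 x n` array, entry `[i, j, ]` = `du_i/dx_j`), `lattice`
#'   metadata (if any) and `n`.
#' @export
velocity_gradient <- function(x, ...) UseMethod("velocity_gradient")

#' @rdname velocity_gradient
#' @export
velocity_gradient.field_snapshot <- function(x, ...) {
  if (is.null(x$lattice))
    stop(paste("snapshot has no lattice metadata: velocity gradients on",
               "unstructured samples are not supported; resample on a",
               "lattice or use the analytic reference"), call. = FALSE)
  dims <- x$lattice$dims
  h <- x$lattice$spacing
  n <- prod(dims)
  stop_if_not(nrow(x$velocity) == n, "velocity length != lattice size")
  tensors <- array(0, c(3, 3, n))
  for (i in 1:3) {
    comp <- array(x$velocity[, i], dim = dims)  # x-fastest ordering
    for (j in 1:3) {
      if (dims[j] < 2) next
      tensors[i, j, ] <- as.vector(.axis_diff(comp, j, h[j]))
    }
  }
  structure(list(tensors = tensors, lattice = x$lattice, n = n),
            class = "gradient_field")
}

#' @rdname velocity_gradient
#' @export
velocity_gradient.analytic_field <- function(x, points = NULL, time = NULL,
                                             ...) {
  if (is.null(points)) points <- x$snapshots[[1]]$locations
  if (is.null(time)) time <- x$times[1]
  tensors <- x$reference$gradient(points, time)
  structure(list(tensors = tensors, lattice = NULL, n = dim(tensors)[3]),
            class = "gradient_field")
}

# finite difference of a 3D array along one axis: central interior,
# one-sided first-order at the two boundary planes
.axis_diff <- function(a, axis, h) {
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  n <- d[1]
  m <- matrix(ap, n)  # rows run along the differenced axis
  out <- matrix(0, n, ncol(m))
  if (n >= 3)
    out[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                           m[1:(n - 2), , drop = FALSE]) / (2 * h)
  out[1, ] <- (m[2, ] - m[1, ]) / h
  out[n, ] <- (m[n, ] - m[n - 1, ]) / h
  aperm(array(out, d), order(perm))
}

#' Q-criterion vortex indicator
#'
#' Second invariant of the velocity-gradient tensor in its standard
#' subtraction form,
#' \deqn{Q = \tfrac12\left(\|\Omega\|_F^2 - \|S\|_F^2\right),}
#' where `S` and `Omega` are the symmetric (strain-rate) and antisymmetric
#' (vorticity) parts of `grad u` and the norms are Frobenius. Connected
#' regions with `Q > 0` mark vortexes; `Q < 0` regions are
#' deformation-dominated and not significant for vortex identification.
#'
#' @param grad a `gradient_field` from [velocity_gradient()].
#' @return numeric vector of per-sample Q values, 1/s^2.
#' @examples
#' fld <- gen_analytic_field(analytic_field_spec("rigid_rotation", rate = 1))
#' unique(round(q_criterion(velocity_gradient(fld)), 12))  # 1
#' @export
q_criterion <- function(grad) {
  stop_if_not(inherits(grad, "gradient_field"), "need a gradient_field")
  A <- grad$tensors
  q <- numeric(grad$n)
  # ||Omega||^2 - ||S||^2 accumulated pairwise: for each unordered (i, j),
  # ((a-b)^2 - (a+b)^2)/2 = -2ab with a = A[i,j,], b = A[j,i,]
  for (i in 1:3) {
    q <- q - 0.5 * A[i, i, ]^2
    if (i < 3) for (j in (i + 1):3) {
      q <- q - A[i, j, ] * A[j, i, ]
    }
  }
  q
}

#' Count connected positive-Q regions on a lattice
#'
#' Labels the `Q > threshold` samples of a lattice field using
#' 6-connectivity (face neighbors) and returns the component count and
#' label array. Deterministic for fixed input and threshold.
#'
#' @param q per-sample Q values in lattice (x-fastest) order.
#' @param dims lattice dimensions `c(nx, ny, nz)`.
#' @param threshold vortex threshold (default 0).
#' @return list with `n` (region count) and `labels` (integer array of
#'   dims `dims`, 0 = not a vortex).
#' @export
vortex_regions <- function(q, dims, threshold = 0) {
  stop_if_not(length(q) == prod(dims), "length(q) != prod(dims)")
  mask <- array(q > threshold, dim = dims)
  labels <- array(0L, dims)
  n <- 0L
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    n <- n + 1L
    stack <- start
    labels[start] <- n
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      k <- (cur - 1L) %/% (nx * ny)
      rem <- (cur - 1L) %% (nx * ny)
      j <- rem %/% nx
      i <- rem %% nx
      for (dd in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                      c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
        ii <- i + dd[1]; jj <- j + dd[2]; kk <- k + dd[3]
        if (ii < 0L || ii >= nx || jj < 0L || jj >= ny ||
            kk < 0L || kk >= nz) next
        nb <- 1L + ii + nx * (jj + ny * kk)
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- n
          stack <- c(stack, nb)
        }
      }
    }
  }
  list(n = n, labels = labels)
}

#' Turbulence intensity
#'
#' `T = sqrt(2 k / 3) / u`, the ratio of the turbulent fluctuation
#' velocity scale to the local instantaneous speed, expressed as a
#' fraction (multiply by 100 for percent). Samples with `u = 0` have
#' undefined intensity; they are returned as `NA` and should be excluded
#' from contour statistics.
#'
#' @param k turbulent kinetic energy, m^2/s^2 (>= 0, vectorized).
#' @param u local velocity magnitude, m/s (vectorized).
#' @return dimensionless intensity values (NA where `u = 0`).
#' @examples
#' turbulence_intensity(0.125, 0.5)  # 0.577
#' @export
turbulence_intensity <- function(k, u) {
  if (any(k < 0)) stop("negative turbulent kinetic energy", call. = FALSE)
  out <- rep(NA_real_, length(u))
  ok <- u != 0
  if (any(!ok))
    warning(sprintf("%d sample(s) with u = 0: intensity undefined (NA)",
                    sum(!ok)))
  out[ok] <- sqrt(2 * rep(k, length.out = length(u))[ok] / 3) / u[ok]
  out
}

#' Axial velocity component and backflow mask
#'
#' Projects the velocity vectors of a snapshot onto a unit axis (the
#' ascending-aorta direction, +z by convention) and flags retrograde
#' samples. When the snapshot carries cross-section area weights, the
#' backflow fraction is area-weighted; otherwise it is the sample
#' fraction.
#'
#' @param snapshot a [field_snapshot()].
#' @param axis unit direction vector, default `c(0, 0, 1)`.
#' @return list with `u_axial` (per-sample axial component, m/s),
#'   `backflow` (logical mask `u_axial < 0`) and `fraction` (backflow
#'   fraction of the cross-section or sample set).
#' @export
axial_backflow <- function(snapshot, axis = c(0, 0, 1)) {
  stop_if_not(inherits(snapshot, "field_snapshot"), "need a field_snapshot")
  stop_if_not(abs(sqrt(sum(axis^2)) - 1) < 1e-8, "'axis' must be unit length")
  uz <- drop(snapshot$velocity %*% axis)
  mask <- uz < 0
  frac <- if (!is.null(snapshot$area_weight)) {
    w <- snapshot$area_weight
    if (sum(w) > 0) sum(w[mask]) / sum(w) else mean(mask)
  } else mean(mask)
  list(u_axial = uz, backflow = mask, fraction = frac)
}
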