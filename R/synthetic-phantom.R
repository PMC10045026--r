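#' Specification of a CT-like lumen phantom
#'
#' Describes a synthetic grayscale image stack emulating a contrast CT
#' acquisition of one or more vessel lumens. Each lumen is an
#' ellipse-section tube whose center drifts linearly across slices
#' (emulating vessel curvature) and whose interior is brighter than the
#' background, as contrast-enhanced blood is on CT. Additive Gaussian noise
#' clipped to the bit-depth range emulates acquisition graininess.
#'
#' @param image_size integer `c(rows, cols)` of every slice.
#' @param n_slices number of slices in the stack.
#' @param pixel_spacing in-plane resolution in mm (> 0).
#' @param slice_thickness slice spacing in mm (> 0).
#' @param lumens list of lumen descriptions, each a list with fields
#'   `center` (`c(row, col)`, 1-based, on the first slice), `drift`
#'   (`c(drow, dcol)` per slice, default `c(0, 0)`), `radii` (scalar radius
#'   or `c(r_row, r_col)` semi-axes in pixels, > 0) and `intensity`
#'   (interior gray level, must exceed `background`).
#' @param background background gray level.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units; 0 disables noise.
#' @param bit_depth bits per pixel; intensities live in `[0, 2^bit_depth - 1]`.
#' @param seed integer seed controlling the noise (default 0).
#' @return an object of class `phantom_spec`.
#' @seealso [gen_phantom_ct()]
#' @export
phantom_spec <- function(image_size = c(128L, 128L), n_slices = 8L,
                         pixel_spacing = 0.9766, slice_thickness = 1.5,
                         lumens = list(list(center = c(64, 64), radii = 20,
                                            intensity = 200)),
                         background = 20, noise_sd = 0, bit_depth = 8L,
                         seed = 0L) {
  stop_if_not(length(image_size) == 2L && all(image_size >= 4),
              "'image_size' must be c(rows, cols) with both >= 4")
  check_scalar(n_slices, "n_slices", positive = TRUE, integer = TRUE)
  check_scalar(pixel_spacing, "pixel_spacing", positive = TRUE)
  check_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(bit_depth, "bit_depth", positive = TRUE, integer = TRUE)
  vmax <- 2^bit_depth - 1
  stop_if_not(background >= 0 && background <= vmax,
              "'background' outside the bit-depth range")
  stop_if_not(is.list(lumens) && length(lumens) >= 1,
              "'lumens' must be a non-empty list")
  lumens <- lapply(lumens, function(lm) {
    stop_if_not(length(lm$center) == 2L, "lumen 'center' must be c(row, col)")
    if (is.null(lm$drift)) lm$drift <- c(0, 0)
    stop_if_not(length(lm$drift) == 2L, "lumen 'drift' must be c(drow, dcol)")
    if (length(lm$radii) == 1L) lm$radii <- rep(lm$radii, 2L)
    stop_if_not(all(lm$radii > 0), "lumen 'radii' must be > 0")
    stop_if_not(is.numeric(lm$intensity) && lm$intensity > background,
                "lumen 'intensity' must exceed the background level")
    stop_if_not(lm$intensity <= vmax, "lumen 'intensity' exceeds bit depth")
    lm
  })
  # every lumen must stay inside the frame on every slice
  for (s in seq_len(n_slices)) {
    for (lm in lumens) {
      ctr <- lm$center + (s - 1) * lm$drift
      if (ctr[1] - lm$radii[1] < 1 || ctr[1] + lm$radii[1] > image_size[1] ||
          ctr[2] - lm$radii[2] < 1 || ctr[2] + lm$radii[2] > image_size[2])
        stop(sprintf(
          "lumen placed outside image bounds on slice %d (center %.1f,%.1f, radii %.1f,%.1f)",
          s, ctr[1], ctr[2], lm$radii[1], lm$radii[2]), call. = FALSE)
    }
  }
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 lumens = lumens, background = background,
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' CT-like image stack container
#'
#' @param intensities 3D array `[row, col, slice]` of integers in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_spacing,slice_thickness physical spacings in mm.
#' @param bit_depth bits per pixel.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(intensities, pixel_spacing, slice_thickness,
                        bit_depth = 8L) {
  stop_if_not(is.array(intensities) && length(dim(intensities)) == 3L,
              "'intensities' must be a 3D array [row, col, slice]")
  check_scalar(pixel_spacing, "pixel_spacing", positive = TRUE)
  check_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  vmax <- 2^bit_depth - 1
  stop_if_not(min(intensities) >= 0 && max(intensities) <= vmax,
              "intensities outside the bit-depth range")
  structure(list(intensities = intensities, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack: %d x %d pixels, %d slices (%g mm / %g mm, %d-bit)\n",
              d[1], d[2], d[3], x$pixel_spacing, x$slice_thickness,
              x$bit_depth))
  invisible(x)
}

# Exact interior test for one lumen on one slice: 1-based pixel centers.
lumen_mask_slice <- function(lm, slice, image_size) {
  ctr <- lm$center + (slice - 1) * lm$drift
  rows <- matrix(seq_len(image_size[1]), image_size[1], image_size[2])
  cols <- matrix(seq_len(image_size[2]), image_size[1], image_size[2],
                 byrow = TRUE)
  ((rows - ctr[1]) / lm$radii[1])^2 + ((cols - ctr[2]) / lm$radii[2])^2 <= 1
}

#' Generate a CT-like phantom with exact ground truth
#'
#' Renders the stack described by a [phantom_spec()]: lumen interiors at
#' their nominal intensity over a uniform background, then seeded Gaussian
#' noise, rounding, and clipping to the bit-depth range. The ground truth
#' (the noise-free interior masks and their boundary-pixel contours) is
#' returned alongside, so segmentation recovery can be scored exactly.
#'
#' A pixel belongs to a lumen when its center satisfies
#' `((row - cr)/r_row)^2 + ((col - cc)/r_col)^2 <= 1`. Ground-truth contours
#' are the foreground pixels with at least one 4-connected background
#' neighbor, grouped by connected component.
#'
#' @param spec a [phantom_spec()].
#' @return a list with components `stack` ([image_stack()]), `truth_masks`
#'   (3D 0/1 array `[row, col, slice]`), and `truth_contours` (per-slice
#'   list of per-component boundary pixel matrices `(row, col)`).
#' @examples
#' ph <- gen_phantom_ct(phantom_spec(noise_sd = 5, seed = 1))
#' dim(ph$stack$intensities)
#' @export
gen_phantom_ct <- function(spec) {
  stop_if_not(inherits(spec, "phantom_spec"), "'spec' must be a phantom_spec")
  sz <- spec$image_size
  vmax <- 2^spec$bit_depth - 1
  imgs <- array(0, c(sz[1], sz[2], spec$n_slices))
  masks <- array(0L, c(sz[1], sz[2], spec$n_slices))
  contours <- vector("list", spec$n_slices)
  for (s in seq_len(spec$n_slices)) {
    img <- matrix(spec$background, sz[1], sz[2])
    msk <- matrix(FALSE, sz[1], sz[2])
    for (lm in spec$lumens) {
      inside <- lumen_mask_slice(lm, s, sz)
      img[inside] <- lm$intensity
      msk <- msk | inside
    }
    imgs[, , s] <- img
    masks[, , s] <- msk * 1L
    comp <- label_components(msk * 1L)
    contours[[s]] <- lapply(seq_len(comp$n), function(i) {
      bp <- boundary_pixels(matrix(as.integer(comp$labels == i), sz[1], sz[2]))
      bp
    })
  }
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    imgs <- imgs + stats::rnorm(length(imgs), 0, spec$noise_sd)
  }
  imgs <- pmin(pmax(round(imgs), 0), vmax)
  list(stack = image_stack(imgs, spec$pixel_spacing, spec$slice_thickness,
                           spec$bit_depth),
       truth_masks = masks, truth_contours = contours)
}

# Save/restore the global RNG state so generators are pure functions of
# their seed and do not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b binary (0/1 or logical) arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stop_if_not(all(dim(a) == dim(b)), "mask shapes differ")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
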