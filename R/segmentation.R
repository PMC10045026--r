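# Minimally supervised lumen segmentation of CT-like slices:
# ROI crop -> histogram equalization -> optional adaptive threshold
# smoothing -> binarization -> Moore-neighbor boundary tracing -> 3D
# point cloud.

#' Histogram equalization of a grayscale slice
#'
#' Classical contrast enhancement: each gray level `v` is mapped to
#' `round((cdf(v) - cdf_min) / (N - cdf_min) * (2^bit_depth - 1))`, where
#' `cdf` is the cumulative pixel-count histogram and `cdf_min` the count at
#' the lowest occupied level. The mapping is monotone (rank-preserving up
#' to ties) and stretches the occupied range to the full bit depth. A
#' constant image has a degenerate histogram and is returned unchanged.
#'
#' @param img integer matrix of intensities.
#' @param bit_depth bits per pixel (defines the output range).
#' @return equalized integer matrix, same shape.
#' @export
equalize_hist <- function(img, bit_depth = 8L) {
  stop_if_not(is.matrix(img), "'img' must be a matrix")
  vmax <- 2^bit_depth - 1
  stop_if_not(min(img) >= 0 && max(img) <= vmax,
              "intensities outside the bit-depth range")
  n <- length(img)
  tab <- tabulate(as.integer(img) + 1L, nbins = vmax + 1L)
  cdf <- cumsum(tab)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min == n) return(img)  # constant image
  lut <- round((cdf - cdf_min) / (n - cdf_min) * vmax)
  out <- matrix(lut[as.integer(img) + 1L], nrow(img), ncol(img))
  out
}

#' Adaptive threshold smoothing filter
#'
#' Background-noise reduction used when lumen visibility is poor. For each
#' pixel, the mean over its 4-connected neighborhood (including the center;
#' replicate padding at the image edges) is compared to `mean_threshold`:
#' where the local mean exceeds it, `decrement` is subtracted from the
#' pixel, clipping at zero.
#'
#' Defaults are 60% of the bit-depth maximum for the threshold and 10% for
#' the decrement; both are tunable.
#'
#' @param img integer matrix.
#' @param mean_threshold local-mean threshold, intensity units (>= 0).
#' @param decrement value subtracted where the local mean is high (>= 0).
#' @param bit_depth used only for the defaults.
#' @return filtered matrix, same shape.
#' @export
adaptive_smooth <- function(img, mean_threshold = 0.6 * (2^bit_depth - 1),
                            decrement = 0.1 * (2^bit_depth - 1),
                            bit_depth = 8L) {
  stop_if_not(is.matrix(img), "'img' must be a matrix")
  check_scalar(mean_threshold, "mean_threshold", nonneg = TRUE)
  check_scalar(decrement, "decrement", nonneg = TRUE)
  nr <- nrow(img); nc <- ncol(img)
  up    <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- img[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  left  <- img[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- img[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  local_mean <- (img + up + down + left + right) / 5
  out <- img
  hit <- local_mean > mean_threshold
  out[hit] <- pmax(img[hit] - decrement, 0)
  out
}

#' Otsu's automatic threshold
#'
#' Maximizes the between-class variance of the intensity histogram. The
#' returned value is meant for [binarize()]'s `>=` convention: pixels at or
#' above it belong to the bright class.
#'
#' @param img integer matrix.
#' @param bit_depth bits per pixel.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(img, bit_depth = 8L) {
  vmax <- 2^bit_depth - 1
  counts <- tabulate(as.integer(img) + 1L, nbins = vmax + 1L)
  levels <- 0:vmax
  n <- sum(counts)
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * levels)
  total <- sum0[length(sum0)]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - sum0) / w1, 0)
  between <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(between)  # split: class 0 is levels <= k-1
  levels[k] + 1
}

#' Binarize a slice by thresholding
#'
#' @param img integer matrix.
#' @param threshold intensity threshold; pixels with `img >= threshold`
#'   map to 1, others to 0.
#' @return 0/1 integer matrix of the same shape.
#' @export
binarize <- function(img, threshold) {
  stop_if_not(is.matrix(img), "'img' must be a matrix")
  check_scalar(threshold, "threshold")
  matrix(as.integer(img >= threshold), nrow(img), ncol(img))
}

#' Label 8-connected foreground components of a binary mask
#'
#' Iterative flood fill (stack-based, no recursion); label 0 is background.
#'
#' @param mask 0/1 matrix.
#' @return list with `labels` (integer matrix) and `n` (component count).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- mask != 0
  n <- 0L
  doff <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  idx_all <- which(fg)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    n <- n + 1L
    stack <- start
    labels[start] <- n
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      for (k in seq_along(doff)) {
        # guard row wrap-around for the +-1 row moves
        nb <- cur + doff[k]
        if (nb < 1L || nb > nr * nc) next
        rn <- ((nb - 1L) %% nr) + 1L
        if (abs(rn - r) > 1L) next
        if (fg[nb] && labels[nb] == 0L) {
          labels[nb] <- n
          stack <- c(stack, nb)
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' Boundary pixels of a binary mask (4-neighbor rule)
#'
#' The brute-force boundary definition used as the tracing oracle:
#' foreground pixels with at least one background 4-neighbor (pixels
#' outside the frame count as background).
#'
#' @param mask 0/1 matrix.
#' @return matrix with columns `row`, `col`, ordered row-major.
#' @export
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- mask != 0
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- fg
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb4 <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- core & !nb4
  m <- which(boundary, arr.ind = TRUE)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  colnames(m) <- c("row", "col")
  m
}

# Moore neighborhood in clockwise order starting at W, as (drow, dcol).
.moore_off <- matrix(c(0L, -1L,  -1L, -1L,  -1L, 0L,  -1L, 1L,
                       0L, 1L,   1L, 1L,    1L, 0L,   1L, -1L),
                     ncol = 2L, byrow = TRUE)

#' Trace lumen boundaries by Moore-neighbor contour following
#'
#' For every 8-connected foreground component of at least `min_size`
#' pixels, walks the outer boundary with the Moore-neighbor tracing
#' algorithm using Jacob's stopping criterion: tracing starts at the
#' topmost, then leftmost pixel of the component (entered from its west
#' neighbor) and terminates when the start pixel is re-entered from that
#' same direction. The Moore neighborhood is scanned clockwise starting
#' from the position after the backtracked background pixel.
#'
#' @param mask 0/1 matrix.
#' @param min_size components smaller than this are discarded (noise
#'   suppression), default 8 pixels.
#' @return list of contours; each contour is a list with `pixels` (ordered
#'   matrix of `(row, col)`, consecutive entries 8-connected, first
#'   reachable from last) and `closed = TRUE`. Empty mask gives an empty
#'   list. An isolated pixel yields a length-1 contour.
#' @export
trace_boundary <- function(mask, min_size = 8L) {
  stop_if_not(is.matrix(mask), "'mask' must be a matrix")
  comp <- label_components(mask)
  out <- list()
  if (comp$n == 0L) return(out)
  sizes <- tabulate(comp$labels[comp$labels > 0L], nbins = comp$n)
  for (ci in seq_len(comp$n)) {
    if (sizes[ci] < min_size) next
    cm <- comp$labels == ci
    out[[length(out) + 1L]] <-
      list(pixels = .moore_trace(cm, 4L * sizes[ci] + 8L), closed = TRUE)
  }
  out
}

# Trace one component. fg: logical matrix; max_steps: termination bound.
# Jacob's stopping criterion is implemented as reproduction of the initial
# tracer state: the walk stops when it is about to re-enter the start pixel
# with the same backtrack pixel it started from, i.e. entered from the same
# direction as the first entry.
.moore_trace <- function(fg, max_steps) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg, arr.ind = TRUE)
  # start: topmost then leftmost pixel; its west neighbor is background
  r0 <- min(idx[, 1L])
  c0 <- min(idx[idx[, 1L] == r0, 2L])
  start <- c(r0, c0)
  start_back <- c(r0, c0 - 1L)
  path <- matrix(start, 1L, 2L)
  cur <- start
  back <- start_back
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) break  # safety; cannot trigger on valid masks
    delta <- back - cur
    b_idx <- which(.moore_off[, 1L] == delta[1L] &
                   .moore_off[, 2L] == delta[2L])
    found <- FALSE
    prev <- back
    for (j in 1:8) {
      k <- ((b_idx - 1L + j) %% 8L) + 1L  # clockwise, starting after backtrack
      nb <- cur + .moore_off[k, ]
      if (nb[1L] >= 1L && nb[1L] <= nr && nb[2L] >= 1L && nb[2L] <= nc &&
          fg[nb[1L], nb[2L]]) {
        if (nb[1L] == start[1L] && nb[2L] == start[2L] &&
            prev[1L] == start_back[1L] && prev[2L] == start_back[2L])
          return(unname(path))  # Jacob: initial state reproduced
        path <- rbind(path, nb)
        back <- prev
        cur <- nb
        found <- TRUE
        break
      }
      prev <- nb
    }
    if (!found) return(unname(path))  # isolated pixel
  }
  unname(path)
}

#' Assemble per-slice contours into a 3D point cloud
#'
#' Maps contour pixels to physical coordinates with the package's
#' convention: `x = (col - 1) * pixel_spacing`,
#' `y = (row - 1) * pixel_spacing`, `z = (slice - 1) * slice_thickness`
#' (1-based indices; slices stacked along z).
#'
#' @param contours_by_slice list indexed by slice; each element a list of
#'   contours as returned by [trace_boundary()] (or plain `(row, col)`
#'   matrices).
#' @param pixel_spacing,slice_thickness physical spacings in mm.
#' @param n_slices if given, slice indices are validated against it.
#' @return object of class `point_cloud`: list with `points` (n x 3 matrix,
#'   columns x/y/z, mm) and `provenance` (data.frame slice, contour).
#' @export
stack_to_cloud <- function(contours_by_slice, pixel_spacing, slice_thickness,
                           n_slices = NULL) {
  check_scalar(pixel_spacing, "pixel_spacing", positive = TRUE)
  check_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  pts <- list(); prov <- list()
  slices <- seq_along(contours_by_slice)
  if (!is.null(n_slices) && length(contours_by_slice) > n_slices)
    stop("slice index outside stack", call. = FALSE)
  for (s in slices) {
    cl <- contours_by_slice[[s]]
    if (is.null(cl)) next
    for (i in seq_along(cl)) {
      px <- if (is.matrix(cl[[i]])) cl[[i]] else cl[[i]]$pixels
      if (is.null(px) || nrow(px) == 0L) next
      pts[[length(pts) + 1L]] <-
        cbind(x = (px[, 2L] - 1) * pixel_spacing,
              y = (px[, 1L] - 1) * pixel_spacing,
              z = rep((s - 1) * slice_thickness, nrow(px)))
      prov[[length(prov) + 1L]] <-
        data.frame(slice = s, contour = i, row = px[, 1L], col = px[, 2L])
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("x", "y", "z")))
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(slice = integer(0), contour = integer(0),
               row = integer(0), col = integer(0))
  structure(list(points = points, provenance = provenance),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points over %d slice(s)\n",
              nrow(x$points), length(unique(x$provenance$slice))))
  invisible(x)
}

#' Full segmentation pipeline: stack to point cloud
#'
#' Composes, per slice: ROI crop, histogram equalization, optional
#' adaptive threshold smoothing (for poor lumen visibility), binarization
#' (automatic Otsu threshold by default), small-component suppression,
#' Moore-neighbor boundary tracing, and point-cloud assembly. Deterministic
#' for a fixed configuration.
#'
#' @param stack an [image_stack()].
#' @param roi `c(row_min, row_max, col_min, col_max)`, 1-based inclusive
#'   bounds; `NULL` uses the whole frame.
#' @param adaptive apply [adaptive_smooth()] after equalization.
#' @param mean_threshold,decrement adaptive-filter constants (defaults 60%
#'   and 10% of the bit-depth maximum).
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param min_size minimum traced component size in pixels.
#' @return list with `cloud` ([stack_to_cloud()] result), `masks` (0/1
#'   array of the full frame with the ROI segmentation embedded), and
#'   `contours` (per-slice contour lists in full-frame pixel coordinates).
#' @examples
#' ph <- gen_phantom_ct(phantom_spec())
#' seg <- segment_pipeline(ph$stack)
#' dice_coefficient(seg$masks, ph$truth_masks)
#' @export
segment_pipeline <- function(stack, roi = NULL, adaptive = FALSE,
                             mean_threshold = NULL, decrement = NULL,
                             threshold = "otsu", min_size = 8L) {
  stop_if_not(inherits(stack, "image_stack"), "'stack' must be an image_stack")
  d <- dim(stack$intensities)
  if (is.null(roi)) roi <- c(1L, d[1], 1L, d[2])
  stop_if_not(length(roi) == 4L && roi[1] >= 1 && roi[2] <= d[1] &&
                roi[3] >= 1 && roi[4] <= d[2] && roi[1] <= roi[2] &&
                roi[3] <= roi[4],
              "'roi' must be c(row_min, row_max, col_min, col_max) within bounds")
  bd <- stack$bit_depth
  if (is.null(mean_threshold)) mean_threshold <- 0.6 * (2^bd - 1)
  if (is.null(decrement)) decrement <- 0.1 * (2^bd - 1)
  masks <- array(0L, d)
  contours <- vector("list", d[3])
  for (s in seq_len(d[3])) {
    raw <- stack$intensities[roi[1]:roi[2], roi[3]:roi[4], s, drop = TRUE]
    raw <- matrix(raw, roi[2] - roi[1] + 1L, roi[4] - roi[3] + 1L)
    img <- equalize_hist(raw, bd)
    if (identical(threshold, "otsu")) {
      # Equalization deliberately flattens the histogram, which starves
      # Otsu of the bimodal structure it needs; since both equalization
      # and thresholding are rank-based, the class split is estimated on
      # the raw crop and transported through the monotone equalization
      # map (the smallest equalized value of any raw pixel at or above
      # the raw split).
      thr_raw <- otsu_threshold(raw, bd)
      above <- img[raw >= thr_raw]
      thr <- if (length(above)) min(above) else 2^bd  # empty bright class
    } else {
      thr <- threshold
    }
    if (adaptive) {
      img <- adaptive_smooth(img, mean_threshold, decrement, bd)
      if (identical(threshold, "otsu")) thr <- thr - decrement
      # the filter lowers high-local-mean (lumen) pixels by `decrement`;
      # untouched background entering the widened band is scattered
      # speckle and falls to the small-component suppression below
    }
    bw <- binarize(img, thr)
    # suppress small specks before tracing
    comp <- label_components(bw)
    if (comp$n > 0L) {
      sizes <- tabulate(comp$labels[comp$labels > 0L], nbins = comp$n)
      drop <- which(sizes < min_size)
      if (length(drop)) bw[comp$labels %in% drop] <- 0L
    }
    masks[roi[1]:roi[2], roi[3]:roi[4], s] <- bw
    cts <- trace_boundary(bw, min_size = min_size)
    contours[[s]] <- lapply(cts, function(ct) {
      ct$pixels[, 1L] <- ct$pixels[, 1L] + roi[1] - 1L
      ct$pixels[, 2L] <- ct$pixels[, 2L] + roi[3] - 1L
      ct
    })
  }
  cloud <- stack_to_cloud(contours, stack$pixel_spacing,
                          stack$slice_thickness, n_slices = d[3])
  list(cloud = cloud, masks = masks, contours = contours)
}
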