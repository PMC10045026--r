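# Segmentation chain: equalization, adaptive smoothing, binarization,
# Moore-neighbor tracing, point-cloud assembly, full pipeline.

test_that("histogram equalization follows the hand-computed CDF mapping", {
  # constant image: degenerate histogram, returned unchanged
  cst <- matrix(37L, 5, 5)
  expect_identical(equalize_hist(cst), cst)
  # 4x4 toy: level 50 on 4 pixels (25%), level 200 on 12 (75%), 8-bit.
  # cdf(50)=4, cdf(200)=16, cdf_min=4:
  #   50  -> round((4-4)/(16-4)*255)  = 0
  #   200 -> round((16-4)/(16-4)*255) = 255
  img <- matrix(200L, 4, 4); img[1, ] <- 50L
  eq <- equalize_hist(img)
  expect_true(all(eq[img == 50] == 0) && all(eq[img == 200] == 255))
  expect_identical(range(eq), c(0, 255))  # full bit-depth range
})

test_that("re-equalizing an equalized ramp moves no pixel more than one step", {
  ramp <- matrix(0:255, 16, 16)  # each 8-bit level exactly once
  once <- equalize_hist(ramp)
  twice <- equalize_hist(once)
  expect_lte(max(abs(twice - once)), 1)
  # monotone rank preservation
  expect_true(all(diff(once[order(ramp)]) >= 0))
})

test_that("adaptive smoothing subtracts only where the local mean is high", {
  u10 <- matrix(10, 5, 5)
  expect_identical(adaptive_smooth(u10, mean_threshold = 100, decrement = 30),
                   u10)
  u200 <- matrix(200, 5, 5)
  # uniform image: every 5-point mean is 200 (replicate padding at edges)
  expect_identical(adaptive_smooth(u200, mean_threshold = 100, decrement = 30),
                   matrix(170, 5, 5))
  set.seed(2)
  any_img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_identical(adaptive_smooth(any_img, mean_threshold = 10, decrement = 0),
                   any_img + 0)  # decrement 0 is the identity
  # clipping at zero
  low <- matrix(5, 4, 4)
  expect_identical(adaptive_smooth(low, mean_threshold = 1, decrement = 30),
                   matrix(0, 4, 4))
})

test_that("binarization thresholds as specified", {
  img <- matrix(50, 3, 3); img[2, 2] <- 200
  expect_identical(binarize(img, 0), matrix(1L, 3, 3))
  expect_identical(binarize(img, 201), matrix(0L, 3, 3))
  m <- binarize(img, 100)
  expect_identical(sum(m), 1L)
  expect_identical(m[2, 2], 1L)
})

test_that("Moore tracing handles the degenerate and hand-enumerable cases", {
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  ct <- trace_boundary(one, min_size = 1)
  expect_length(ct, 1L)
  expect_identical(nrow(ct[[1]]$pixels), 1L)
  # 3x3 filled block: the 8 border pixels in one clockwise loop
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  ct <- trace_boundary(sq, min_size = 1)
  expect_length(ct, 1L)
  px <- ct[[1]]$pixels
  expect_identical(nrow(px), 8L)  # center pixel not on the boundary
  # consecutive pixels 8-connected, loop closes
  steps <- rbind(diff(px), px[1, ] - px[nrow(px), ])
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))
  # starts at topmost-leftmost
  expect_identical(px[1, ], c(2L, 2L))
  expect_setequal(paste(px[, 1], px[, 2]),
                  paste(boundary_pixels(sq)[, 1], boundary_pixels(sq)[, 2]))
})

test_that("traced contours equal the brute-force boundary set on disks and blobs", {
  mk_disk <- function(n, r) {
    rows <- matrix(seq_len(n), n, n); cols <- t(rows)
    ((rows - (n + 1) / 2)^2 + (cols - (n + 1) / 2)^2 <= r^2) * 1L
  }
  disk <- mk_disk(48, 20)
  ct <- trace_boundary(disk)
  expect_length(ct, 1L)
  px <- unique(ct[[1]]$pixels)
  bp <- boundary_pixels(disk)
  expect_setequal(paste(px[, 1], px[, 2]), paste(bp[, 1], bp[, 2]))
  # every contour pixel has a background 4-neighbor
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; c <- px[i, 2]
    nb <- c(disk[r - 1, c], disk[r + 1, c], disk[r, c - 1], disk[r, c + 1])
    expect_true(any(nb == 0))
  }
  # contour length is close to the continuum circumference 2 pi r
  expect_lt(abs(nrow(ct[[1]]$pixels) - 2 * pi * 20) / (2 * pi * 20), 0.15)
  # seeded random blob masks: oracle equivalence and guaranteed termination
  set.seed(42)
  for (rep in 1:8) {
    m <- random_blob_mask()
    cts <- trace_boundary(m, min_size = 1)
    traced <- do.call(rbind, lapply(cts, function(ct) ct$pixels))
    bp <- boundary_pixels(m)
    expect_setequal(paste(traced[, 1], traced[, 2]),
                    paste(bp[, 1], bp[, 2]))
    # Jacob termination bound: path length <= 4 x foreground count
    expect_lte(max(vapply(cts, function(ct) nrow(ct$pixels), 1L)),
               4L * sum(m))
  }
  expect_length(trace_boundary(matrix(0L, 4, 4)), 0L)
})

test_that("stack_to_cloud maps pixels with the stated coordinate convention", {
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  ct <- trace_boundary(sq, min_size = 1)
  cl1 <- stack_to_cloud(list(ct), pixel_spacing = 0.8, slice_thickness = 1.5)
  expect_identical(nrow(cl1$points), 8L)
  expect_true(all(cl1$points[, "z"] == 0))
  expect_equal(cl1$points[1, ], c(x = 0.8, y = 0.8, z = 0))  # pixel (2,2)
  # same contour on slice 4 (three thicknesses above slice 1): z = 4.5 mm
  cl4 <- stack_to_cloud(list(NULL, NULL, NULL, ct), 0.8, 1.5)
  expect_true(all(cl4$points[, "z"] == 4.5))
  empty <- stack_to_cloud(list(), 0.8, 1.5)
  expect_identical(nrow(empty$points), 0L)
  expect_error(stack_to_cloud(list(NULL, ct), 0.8, 1.5, n_slices = 1),
               "outside stack")
})

test_that("pipeline recovers a noiseless phantom nearly exactly", {
  ph <- gen_phantom_ct(phantom_spec(image_size = c(96, 96), n_slices = 3,
    lumens = list(list(center = c(48, 48), radii = 18, intensity = 200))))
  seg <- segment_pipeline(ph$stack)
  expect_gte(dice_coefficient(seg$masks, ph$truth_masks), 0.99)
})

test_that("pipeline separates a two-lumen phantom into 2 contours per slice", {
  ph <- gen_phantom_ct(phantom_spec(image_size = c(96, 96), n_slices = 3,
    lumens = list(
      list(center = c(48, 30), radii = 12, intensity = 200),
      list(center = c(48, 56), radii = 12, intensity = 190))))
  seg <- segment_pipeline(ph$stack)
  for (s in 1:3) expect_length(seg$contours[[s]], 2L)
})

test_that("adaptive smoothing rescues a noisy phantom to Dice >= 0.95", {
  ph <- gen_phantom_ct(phantom_spec(image_size = c(96, 96), n_slices = 3,
    noise_sd = 5, seed = 1,
    lumens = list(list(center = c(48, 48), radii = 18, intensity = 200))))
  seg <- segment_pipeline(ph$stack, adaptive = TRUE)
  expect_gte(dice_coefficient(seg$masks, ph$truth_masks), 0.95)
})

test_that("pipeline is deterministic and invariant to monotone rescaling", {
  ph <- gen_phantom_ct(phantom_spec(image_size = c(64, 64), n_slices = 2,
    noise_sd = 3, seed = 5,
    lumens = list(list(center = c(32, 32), radii = 12, intensity = 200))))
  s1 <- segment_pipeline(ph$stack, roi = c(8, 60, 8, 60))
  s2 <- segment_pipeline(ph$stack, roi = c(8, 60, 8, 60))
  expect_identical(s1$cloud$points, s2$cloud$points)
  # a strictly increasing same-depth intensity map (shift by +40, no
  # clipping at this phantom's intensity range) preserves the histogram
  # structure, so the rank-based pipeline returns the identical cloud
  expect_lte(max(ph$stack$intensities) + 40, 255)
  shifted <- image_stack(ph$stack$intensities + 40, 0.9766, 1.5, 8L)
  s3 <- segment_pipeline(shifted, roi = c(8, 60, 8, 60))
  expect_identical(s1$cloud$points, s3$cloud$points)
})

test_that("bad ROIs are rejected", {
  ph <- gen_phantom_ct(phantom_spec(image_size = c(32, 32), n_slices = 1,
    lumens = list(list(center = c(16, 16), radii = 6, intensity = 200))))
  expect_error(segment_pipeline(ph$stack, roi = c(0, 32, 1, 32)), "roi")
  expect_error(segment_pipeline(ph$stack, roi = c(1, 40, 1, 32)), "roi")
})
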