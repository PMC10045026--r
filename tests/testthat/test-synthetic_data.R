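# Generators: CT phantoms, analytic fields, inlet/outlet waveforms.

test_that("noiseless phantom equals its own ground truth", {
  spec <- phantom_spec(image_size = c(64, 64), n_slices = 2,
                       lumens = list(list(center = c(32, 32), radii = 10,
                                          intensity = 200)),
                       noise_sd = 0)
  ph <- gen_phantom_ct(spec)
  # truth mask is exactly the set of pixels with center distance <= 10
  rows <- matrix(1:64, 64, 64); cols <- t(rows)
  expected <- ((rows - 32)^2 + (cols - 32)^2 <= 100) * 1L
  expect_identical(ph$truth_masks[, , 1], expected)
  # noiseless image is two-level: lumen intensity inside, background outside
  expect_true(all(ph$stack$intensities[, , 1][expected == 1] == 200))
  expect_true(all(ph$stack$intensities[, , 1][expected == 0] == 20))
})

test_that("two-lumen phantom with a septum has two disjoint components", {
  spec <- phantom_spec(image_size = c(96, 96), n_slices = 3,
                       lumens = list(
                         list(center = c(48, 30), radii = 12, intensity = 200),
                         list(center = c(48, 56), radii = 12, intensity = 180)))
  # septum: gap between lumen edges = 56 - 30 - 24 = 2 px
  ph <- gen_phantom_ct(spec)
  for (s in 1:3) {
    comp <- label_components(ph$truth_masks[, , s])
    expect_identical(comp$n, 2L)
    expect_length(ph$truth_contours[[s]], 2L)
  }
})

test_that("phantom noise is bit-exactly reproducible under the seed", {
  mk <- function(seed) gen_phantom_ct(phantom_spec(
    image_size = c(48, 48), n_slices = 2, noise_sd = 5, seed = seed,
    lumens = list(list(center = c(24, 24), radii = 10, intensity = 200))))
  a <- mk(7); b <- mk(7); c <- mk(8)
  expect_identical(a$stack$intensities, b$stack$intensities)
  expect_false(identical(a$stack$intensities, c$stack$intensities))
  # truth is noise-free hence seed-invariant
  expect_identical(a$truth_masks, c$truth_masks)
})

test_that("out-of-bounds lumens and bad specs are rejected", {
  expect_error(phantom_spec(image_size = c(32, 32),
                            lumens = list(list(center = c(16, 16), radii = 20,
                                               intensity = 200))),
               "outside image bounds")
  # drift carries the lumen out on a later slice
  expect_error(phantom_spec(image_size = c(64, 64), n_slices = 10,
                            lumens = list(list(center = c(32, 32), radii = 10,
                                               drift = c(0, 3),
                                               intensity = 200))),
               "outside image bounds")
  expect_error(phantom_spec(lumens = list(list(center = c(64, 64), radii = 10,
                                               intensity = 10))),
               "exceed the background")
})

test_that("poiseuille field carries the closed-form wall shear", {
  fld <- gen_analytic_field(analytic_field_spec("poiseuille",
                                                radius = 0.0175,
                                                u_mean = 0.25))
  ref <- 4 * 3.71e-3 * 0.25 / 0.0175  # 4 mu u_mean / R = 0.212 Pa
  expect_equal(fld$reference$wall_shear_scalar(0), ref, tolerance = 1e-12)
  w <- fld$reference$wall_shear(0)
  expect_true(all(abs(sqrt(rowSums(w^2)) - ref) < 1e-12))
})

test_that("rigid rotation reference gradient is antisymmetric +-rate", {
  fld <- gen_analytic_field(analytic_field_spec("rigid_rotation", rate = 1))
  g <- fld$reference$gradient(fld$snapshots[[1]]$locations, 0)
  expect_true(all(g[1, 2, ] == -1) && all(g[2, 1, ] == 1))
  expect_true(all(g[1, 1, ] == 0) && all(g[2, 2, ] == 0) &&
                all(g[3, 3, ] == 0))
  sym <- g + aperm(g, c(2, 1, 3))  # S part vanishes for rigid rotation
  expect_true(max(abs(sym)) == 0)
})

test_that("womersley with a single zero-frequency harmonic degenerates to poiseuille", {
  mu <- 3.71e-3; R <- 0.0175; um <- 0.25
  h0 <- data.frame(amplitude = 8 * mu * um / R^2, phase = 0, frequency = 0)
  fw <- gen_analytic_field(analytic_field_spec("womersley", harmonics = h0,
                                               radius = R))
  fp <- gen_analytic_field(analytic_field_spec("poiseuille", radius = R,
                                               u_mean = um))
  expect_equal(fw$reference$wall_shear_scalar(0),
               fp$reference$wall_shear_scalar(0), tolerance = 1e-10)
  expect_equal(fw$snapshots[[1]]$velocity, fp$snapshots[[1]]$velocity,
               tolerance = 1e-10)
})

test_that("analytic reference gradients are divergence-free for all kinds", {
  specs <- list(
    analytic_field_spec("poiseuille"),
    analytic_field_spec("womersley",
      harmonics = data.frame(amplitude = c(50, 30), phase = c(0, 1),
                             frequency = c(0, 1 / 0.96)), n_time = 4),
    analytic_field_spec("rigid_rotation", rate = 2),
    analytic_field_spec("pure_shear", gamma = 3))
  set.seed(11)
  pts <- cbind(stats::runif(50, -0.01, 0.01), stats::runif(50, -0.01, 0.01),
               stats::runif(50, 0, 0.02))
  for (sp in specs) {
    fld <- gen_analytic_field(sp)
    g <- fld$reference$gradient(pts, 0.1)
    div <- g[1, 1, ] + g[2, 2, ] + g[3, 3, ]
    expect_lt(max(abs(div)), 1e-10)
  }
})

test_that("womersley reference wall shear is periodic with the waveform period", {
  h <- data.frame(amplitude = c(40, 25), phase = c(0.3, 1.2),
                  frequency = c(1 / 0.96, 2 / 0.96))
  fld <- gen_analytic_field(analytic_field_spec("womersley", harmonics = h,
                                                n_time = 8))
  expect_equal(fld$period, 0.96)
  for (t in c(0, 0.2, 0.53))
    expect_equal(fld$reference$wall_shear_scalar(t),
                 fld$reference$wall_shear_scalar(t + 0.96),
                 tolerance = 1e-9)
})

test_that("inlet waveform hits its printed summary constraints", {
  wf <- gen_inlet_waveform(period = 0.96, peak = 0.5, mean_velocity = 0.104,
                           backflow_depth = 0.05)
  expect_equal(max(wf$values), 0.5, tolerance = 0.02)
  expect_equal(mean(wf$values), 0.104, tolerance = 0.02)
  expect_true(any(wf$values < 0))
  # mean flow through a 3.5 cm diameter inlet in L/min
  flow_lmin <- mean(wf$values) * pi * 0.0175^2 * 6e4
  expect_equal(flow_lmin, 6, tolerance = 0.02)
})

test_that("waveform backflow switch and determinism behave", {
  wf0 <- gen_inlet_waveform(backflow_depth = 0)
  expect_true(all(wf0$values >= 0))
  a <- gen_inlet_waveform(noise_sd = 0.01, seed = 3)
  b <- gen_inlet_waveform(noise_sd = 0.01, seed = 3)
  expect_identical(a$values, b$values)
  expect_error(gen_inlet_waveform(peak = 0.5, mean_velocity = 0.6),
               "mean_velocity < peak")
  # a mean this close to zero cannot stay non-negative with this template
  expect_error(gen_inlet_waveform(peak = 0.5, mean_velocity = 0.004,
                                  backflow_depth = 0),
               "infeasible")
})

test_that("outlet flow generator shapes and contracts hold", {
  cst <- gen_outlet_flow("constant", level = 1e-4, n_samples = 16)
  expect_true(all(cst$values == 1e-4))
  hs <- gen_outlet_flow("half_sine", amplitude = 2e-4,
                        systole_fraction = 0.35, period = 0.96,
                        n_samples = 4096)
  expect_true(all(hs$values >= 0))
  # pulse integral: quadrature vs closed form A * fs * T * 2 / pi
  integral <- trapz_periodic_oracle(hs$values, 0.96)
  expect_equal(integral, 2e-4 * 0.35 * 0.96 * 2 / pi, tolerance = 1e-5)
  expect_identical(gen_outlet_flow("half_sine", noise_sd = 1e-6, seed = 4)$values,
                   gen_outlet_flow("half_sine", noise_sd = 1e-6, seed = 4)$values)
  expect_error(gen_outlet_flow("constant", n_samples = 1), "n_samples")
})
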