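test_that("parallel planes give the plane separation at every node", {
  up <- surface_from_function(function(x, y) rep(300, length(x)), mask_radius = 2700)
  lo <- surface_from_function(function(x, y) rep(415, length(x)))
  tm <- raytrace_thickness(up, lo, "full_cornea")
  expect_lt(max(abs(tm$thickness[tm$mask] - 115)), 1e-5)
  expect_equal(tm$n_failed, 0)
})

test_that("concentric spheres give the radius difference at every valid node", {
  cz <- 7800  # common centre depth; radii 7015 (upper) / 7000 (lower)
  up <- surface_from_function(function(x, y) cz - sqrt(7015^2 - x^2 - y^2),
                              mask_radius = 2700)
  lo <- surface_from_function(function(x, y) cz - sqrt(7000^2 - x^2 - y^2))
  tm <- raytrace_thickness(up, lo, "EnDM")
  expect_lt(max(abs(tm$thickness[tm$mask] - 15)), 1e-3)
})

test_that("a tilted layer is measured along the normal, not vertically", {
  d <- 100; th <- 10 * pi / 180
  up <- surface_from_function(function(x, y) 300 + tan(th) * x, mask_radius = 2500)
  lo <- surface_from_function(function(x, y) 300 + d + tan(th) * x)
  tm <- raytrace_thickness(up, lo, "full_cornea")
  expect_lt(max(abs(tm$thickness[tm$mask] - d * cos(th))), 1e-4)
})

test_that("central means average valid nodes inside the zone", {
  up <- surface_from_function(function(x, y) rep(300, length(x)))
  lo <- surface_from_function(function(x, y) rep(315, length(x)))
  tm <- raytrace_thickness(up, lo, "EnDM")
  expect_equal(central_mean(tm)$mean_um, 15, tolerance = 1e-6)
  # a field linear in x on a symmetric grid averages to its centre value
  tm2 <- tm
  X <- matrix(tm$x, length(tm$x), length(tm$y))
  tm2$thickness <- 15 + 0.01 * X
  expect_equal(central_mean(tm2)$mean_um, 15, tolerance = 1e-9)
  expect_equal(central_mean(tm2, center = c(500, 0))$mean_um, 20, tolerance = 1e-9)
  tm2$mask[] <- FALSE
  expect_error(central_mean(tm2), "no valid nodes")
})

test_that("excrescence-thickened phantoms match the independent quadrature oracle", {
  spec <- phantom_spec(excrescences = data.frame(
    position_mm = c(0, 0.6), height_um = c(8, 6), width_um = c(200, 250)))
  truth <- make_phantom(spec)
  up <- surface_from_function(truth$interfaces$endm_anterior, mask_radius = 2700)
  lo <- surface_from_function(truth$interfaces$posterior)
  tm <- raytrace_thickness(up, lo, "EnDM")
  oracle <- oracle_central_thickness(truth, "endm_anterior")
  expect_equal(central_mean(tm)$mean_um, oracle, tolerance = 0.5)
})

test_that("En/DM thickness is contained in the full corneal thickness", {
  cs <- noiseless_case()
  bset <- segment_volume(cs$volume)
  surf <- lapply(c(anterior = "anterior", endm_anterior = "endm_anterior",
                   posterior = "posterior"),
                 function(i) fit_surface_bicubic(boundaries_to_points(bset, i)))
  endm <- raytrace_thickness(surf$endm_anterior, surf$posterior, "EnDM")
  cct <- raytrace_thickness(surf$anterior, surf$posterior, "full_cornea")
  sel <- endm$mask & cct$mask
  expect_true(all(endm$thickness[sel] > 0))
  expect_true(all(endm$thickness[sel] < cct$thickness[sel]))
})

test_that("measure_visit recovers the phantom truth", {
  cs <- noiseless_case()
  m0 <- measure_visit(cs$volume)
  expect_lt(abs(m0$endmt_um - cs$truth$endmt_central), 0.2)
  expect_lt(abs(m0$cct_um - cs$truth$cct_central), 3)
  # moderate speckle
  spec <- phantom_spec(speckle_sigma = 0.2, seed = 5)
  truth <- make_phantom(spec)
  m1 <- measure_visit(small_volume(spec, truth))
  expect_lt(abs(m1$endmt_um - truth$endmt_central), 1)
  expect_lt(abs(m1$cct_um - truth$cct_central), 3)
  # added central excrescences can only thicken the measured En/DM
  spec_b <- phantom_spec(excrescences = data.frame(
    position_mm = c(0, 0.3, 0.6), height_um = 8, width_um = 200))
  m2 <- measure_visit(small_volume(spec_b, make_phantom(spec_b)))
  expect_gt(m2$endmt_um, m0$endmt_um)
})

test_that("the central mean is stable under cut-angle rotation and grid refinement", {
  cs <- noiseless_case()
  m0 <- measure_visit(cs$volume)
  vol_rot <- render_volume(cs$truth, cs$spec, n_scans = 4L, width = 256L,
                           angle_offset_deg = 10)
  m_rot <- measure_visit(vol_rot)
  expect_lt(abs(m_rot$endmt_um - m0$endmt_um), 0.1)
  m_fine <- measure_visit(cs$volume, spacing = 25)
  expect_lt(abs(m_fine$endmt_um - m0$endmt_um), 0.05)
})
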