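test_that("ground truth carries the constructed geometry and rejects invalid specs", {
  spec <- phantom_spec(anterior_radius = 7800, posterior_radius = 6500,
                       endmt_true = 15)
  truth <- make_phantom(spec)
  expect_equal(truth$endmt_central, 15, tolerance = 1e-9)
  expect_gt(truth$cct_central, spec$cct_apex)  # off-apex normal CCT exceeds apex value
  # ordering holds across the aperture
  r <- seq(0, 3000, length.out = 50)
  expect_true(all(truth$profiles$anterior(r) < truth$profiles$endm_anterior(r)))
  expect_true(all(truth$profiles$endm_anterior(r) < truth$profiles$posterior(r)))

  expect_error(phantom_spec(endmt_true = 0), "endmt_true")
  expect_error(phantom_spec(anterior_radius = 6000, posterior_radius = 6500),
               "posterior_radius")
  expect_error(phantom_spec(outlier_column_fraction = 1), "outlier_column_fraction")
  expect_error(phantom_spec(band_intensity = 1.2), "band_intensity")
  # an excrescence tall enough to pierce the anterior surface violates ordering
  expect_error(make_phantom(phantom_spec(excrescences = data.frame(
    position_mm = 0, height_um = 700, width_um = 400))), "ordering")
})

test_that("excrescences thicken the true central En/DM by the quadrature amount", {
  spec <- phantom_spec(excrescences = data.frame(position_mm = 0, height_um = 10,
                                                 width_um = 200))
  truth <- make_phantom(spec)
  expect_gt(truth$endmt_central, 15)
  oracle <- oracle_central_thickness(truth, "endm_anterior")
  expect_equal(truth$endmt_central, oracle, tolerance = 0.02)
})

test_that("noiseless rendering places band peaks exactly on ground-truth rows", {
  cs <- noiseless_case()
  vol <- cs$volume
  tr <- truth_interface_rows(cs$truth, vol)
  w <- ncol(vol$bscans[[1]])
  for (s in seq_along(vol$bscans)) {
    img <- vol$bscans[[s]]
    cols <- setdiff(seq(10, w - 10, by = 7), vol$vertex_column)
    for (intf in c("anterior", "endm_anterior", "posterior")) {
      mu <- tr[[s]][cols, intf]
      # intensity argmax in each band's neighbourhood equals the truth row
      hits <- vapply(seq_along(cols), function(i) {
        win <- max(1, round(mu[i]) - 4):min(nrow(img), round(mu[i]) + 4)
        win[which.max(img[win, cols[i]])]
      }, numeric(1))
      expect_equal(hits, round(mu), tolerance = 0)
    }
  }
})

test_that("rendering is deterministic, band-ordered, and geometrically consistent", {
  cs <- noiseless_case()
  vol2 <- small_volume(cs$spec, cs$truth)
  expect_identical(cs$volume$bscans, vol2$bscans)
  # a different seed changes a noisy render
  spec_a <- phantom_spec(speckle_sigma = 0.2, seed = 1)
  spec_b <- phantom_spec(speckle_sigma = 0.2, seed = 2)
  tr <- make_phantom(spec_a)
  expect_false(identical(small_volume(spec_a, tr)$bscans,
                         small_volume(spec_b, make_phantom(spec_b))$bscans))
  # lateral extent covers the 6-mm scan width
  w <- ncol(cs$volume$bscans[[1]])
  expect_equal(w * cs$volume$lateral_um_per_px, 6000)
  # saturation column is clipped bright
  expect_true(all(cs$volume$bscans[[1]][, cs$volume$vertex_column] == 1))
})

test_that("under speckle the band peaks stay within 2 px of truth for 95% of columns", {
  spec <- phantom_spec(speckle_sigma = 0.3, seed = 11)
  truth <- make_phantom(spec)
  vol <- small_volume(spec, truth)
  tr <- truth_interface_rows(truth, vol)
  w <- ncol(vol$bscans[[1]])
  ok <- 0L; tot <- 0L
  for (s in seq_along(vol$bscans)) {
    img <- vol$bscans[[s]]
    cols <- setdiff(seq(5, w - 5), vol$vertex_column)
    for (intf in c("anterior", "endm_anterior", "posterior")) {
      mu <- tr[[s]][cols, intf]
      hits <- vapply(seq_along(cols), function(i) {
        win <- max(1, round(mu[i]) - 6):min(nrow(img), round(mu[i]) + 6)
        win[which.max(img[win, cols[i]])]
      }, numeric(1))
      ok <- ok + sum(abs(hits - mu) <= 2)
      tot <- tot + length(cols)
    }
  }
  expect_gte(ok / tot, 0.95)
})

test_that("outlier columns are rendered grossly displaced", {
  cs <- noisy_case()
  vol <- cs$volume
  tr <- truth_interface_rows(cs$truth, vol)
  oc <- vol$metadata$outlier_columns[[1]]
  expect_gt(length(oc), 0)
  img <- vol$bscans[[1]]
  mu <- tr[[1]][oc, "posterior"]
  # displaced bands: nothing near the true posterior row in most outlier columns
  displaced <- vapply(seq_along(oc), function(i) {
    win <- max(1, round(mu[i]) - 10):min(nrow(img), round(mu[i]) + 10)
    max(img[win, oc[i]]) < 0.3 ||
      abs(win[which.max(img[win, oc[i]])] - mu[i]) > 5
  }, logical(1))
  expect_gt(mean(displaced), 0.5)
})
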