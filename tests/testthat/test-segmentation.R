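cfg <- segmentation_config()

test_that("isolated bands yield one candidate per interface at the right rows", {
  img <- matrix(0.01, 400, 40)
  img[50, ] <- 1; img[200, ] <- 1; img[210, ] <- 1
  img[200, 25] <- 0.01  # column 25 has only two bands
  cand <- detect_bands(img, cfg, vertex_column = 1L)
  c10 <- cand[cand$column == 10, ]
  expect_equal(c10$interface, c("anterior", "endm_anterior", "posterior"))
  expect_equal(c10$row, c(50, 200, 210), tolerance = 0.6)
  expect_equal(nrow(cand[cand$column == 25, ]), 0)
  expect_false(1L %in% cand$column)  # vertex column contributes nothing
})

test_that("an all-zero scan warns and returns an empty candidate set", {
  expect_warning(cand <- detect_bands(matrix(0, 64, 8), cfg, 4L), "all-zero")
  expect_equal(nrow(cand), 0)
  expect_true(attr(cand, "flag_empty_image"))
})

test_that("noiseless phantom candidates coincide with ground-truth interface rows", {
  cs <- noiseless_case()
  vol <- cs$volume
  tr <- truth_interface_rows(cs$truth, vol)
  cand <- detect_bands(vol$bscans[[1]], cfg, vol$vertex_column)
  for (intf in c("anterior", "endm_anterior", "posterior")) {
    ci <- cand[cand$interface == intf, ]
    expect_gt(nrow(ci), 200)
    expect_lt(max(abs(ci$row - tr[[1]][ci$column, intf])), 0.05)
  }
})

test_that("RANSAC reproduces exact and least-squares fits on clean data", {
  cfg2 <- segmentation_config(poly_degree = 2)
  pts <- data.frame(column = 1:50, row = rep(5, 50))
  fit <- ransac_fit(pts, cfg2)
  expect_equal(fit$coefficients, c(5, 0, 0), tolerance = 1e-9)
  expect_true(all(fit$inlier_mask))
  # with zero outliers the consensus refit equals direct least squares
  for (s in 1:5) {
    set.seed(s)
    u <- seq(-1, 1, length.out = 120)
    y <- 80 + 10 * u - 25 * u^2 + rnorm(120, 0, 0.3)
    pts <- data.frame(column = seq_along(u), row = y)
    fit <- ransac_fit(pts, cfg2, seed = s)
    ols <- ols_poly(u, y, 2)
    expect_lt(max(abs(fit$coefficients - ols)) / max(abs(ols)), 1e-6)
  }
})

test_that("RANSAC recovers the clean model under gross outliers", {
  set.seed(42)
  cfg2 <- segmentation_config(poly_degree = 2)
  u <- seq(-1, 1, length.out = 100)
  clean <- 100 + 30 * u^2
  y <- clean
  out_idx <- sample(100, 20)
  y[out_idx] <- y[out_idx] + 50 * sample(c(-1, 1), 20, replace = TRUE)
  fit <- ransac_fit(data.frame(column = seq_along(u), row = y), cfg2, seed = 3)
  oracle <- ols_poly(u[-out_idx], y[-out_idx], 2)
  expect_lt(max(abs(fit$coefficients - oracle) / pmax(abs(oracle), 1)), 0.01)
  expect_false(any(fit$inlier_mask[out_idx]))
  expect_error(ransac_fit(data.frame(column = 1:2, row = 1:2), cfg2),
               "insufficient candidates")
})

test_that("consensus excludes every displaced outlier across seeds", {
  cfg2 <- segmentation_config(poly_degree = 2, inlier_threshold_px = 2)
  success <- vapply(1:20, function(s) {
    set.seed(s)
    u <- seq(-1, 1, length.out = 90)
    y <- 120 + 20 * u + 15 * u^2 + rnorm(90, 0, 0.3)
    out_idx <- sample(90, 27)  # 30% outliers, displaced >= 10x threshold
    y[out_idx] <- y[out_idx] + runif(27, 20, 60) * sample(c(-1, 1), 27, TRUE)
    fit <- ransac_fit(data.frame(column = seq_along(u), row = y), cfg2, seed = s)
    !any(fit$inlier_mask[out_idx])
  }, logical(1))
  expect_gte(mean(success), 0.95)
})

test_that("segmentation is deterministic and accurate on the noiseless phantom", {
  cs <- noiseless_case()
  b1 <- segment_volume(cs$volume, cfg)
  b2 <- segment_volume(cs$volume, cfg)
  expect_identical(b1$scans, b2$scans)
  tr <- truth_interface_rows(cs$truth, cs$volume)
  w <- ncol(cs$volume$bscans[[1]])
  for (s in seq_along(b1$scans)) {
    expect_length(b1$scans[[s]]$flags, 0)
    for (intf in c("anterior", "endm_anterior", "posterior")) {
      cols <- setdiff(seq(15, w - 15), cs$volume$vertex_column)
      rmse <- sqrt(mean((predict_boundary(b1$scans[[s]]$fits[[intf]], cols) -
                           tr[[s]][cols, intf])^2))
      expect_lt(rmse, 0.5)
    }
  }
})

test_that("grossly displaced candidates are excluded from the consensus inlier sets", {
  cs <- noisy_case()
  bset <- segment_volume(cs$volume, cfg)
  tr <- truth_interface_rows(cs$truth, cs$volume)
  n_displaced <- 0L
  for (s in seq_along(bset$scans)) {
    oc <- cs$volume$metadata$outlier_columns[[s]]
    for (intf in c("anterior", "endm_anterior", "posterior")) {
      fit <- bset$scans[[s]]$fits[[intf]]
      at_out <- which(fit$columns %in% oc)
      if (!length(at_out)) next
      dev <- abs(fit$rows[at_out] - tr[[s]][fit$columns[at_out], intf])
      displaced <- dev > 3
      n_displaced <- n_displaced + sum(displaced)
      expect_false(any(fit$inlier_mask[at_out][displaced]))
    }
  }
  expect_gt(n_displaced, 20)  # the condition actually exercised gross outliers
})

test_that("manual edits are honoured by the refit", {
  cs <- noiseless_case()
  base <- segment_volume(cs$volume, cfg)
  edit_cols <- c(60, 90, 120, 150, 180)
  orig <- predict_boundary(base$scans[[1]]$fits$endm_anterior, edit_cols)
  edits <- tibble::tibble(scan = 1L, interface = "endm_anterior",
                          column = edit_cols, row = orig + 20)
  edited <- segment_volume(cs$volume, cfg, edits = edits)
  fit <- edited$scans[[1]]$fits$endm_anterior
  expect_lt(max(abs(predict_boundary(fit, edit_cols) - (orig + 20))),
            cfg$inlier_threshold_px)
  # edits CSV reader round-trips the override table
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(edits, p, row.names = FALSE)
  expect_equal(as.data.frame(read_edits(p)), as.data.frame(edits))
})
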