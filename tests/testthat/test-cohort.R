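test_that("default simulation reproduces the cohort structure deterministically", {
  cfg <- cohort_config(seed = 3)
  co <- simulate_cohort(cfg)
  pat <- dplyr::distinct(tibble::as_tibble(co)[, c("patient_id", "group")])
  expect_equal(sum(pat$group == "rejected"), 21)
  expect_equal(sum(pat$group == "clear"), 39)
  expect_identical(simulate_cohort(cfg), co)
  expect_false(identical(simulate_cohort(cohort_config(seed = 4))$endmt_um, co$endmt_um))
  # degenerate config: no rejections, no event rows
  co0 <- simulate_cohort(cohort_config(n_reject = 0, seed = 1))
  expect_true(all(co0$group == "clear"))
  expect_true(all(is.na(co0$rejection_month)))
})

test_that("schedule and threshold invariants hold across seeds", {
  for (s in c(2, 10, 20)) {
    co <- simulate_cohort(cohort_config(seed = s))
    expect_true(all(co$visit_month %in% c(1, 3, 6, 9, 12)))
    ev <- co$rejection_month[!is.na(co$rejection_month)]
    expect_true(all(ev > 0 & ev <= 15))
    # rejected series are strictly pre-rejection
    rej <- co[co$group == "rejected", ]
    expect_true(all(rej$visit_month < rej$rejection_month))
    # no never-flagged clear graft exceeds 17 um
    unflagged <- tibble::as_tibble(co) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::filter(.data$group == "clear", all(.data$endmt_um < 19))
    expect_true(all(unflagged$endmt_um < 17))
  }
})

test_that("flag-rate calibration is recovered on average over 100 seeds", {
  rates <- vapply(1:100, function(s) {
    fr <- flag_rates(simulate_cohort(cohort_config(seed = s)), 19)
    c(fr$rejected_flagged, fr$clear_flagged)
  }, numeric(2))
  expect_lt(abs(mean(rates[1, ]) - 17 / 21), 0.1)
  expect_lt(abs(mean(rates[2, ]) - 7 / 39), 0.1)
})

test_that("the packaged fixture regenerates byte-identically and hits its counts", {
  fx <- fixture_default()
  shipped <- system.file("extdata", "fixture_cohort.csv", package = "endmtrack")
  expect_true(nzchar(shipped))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(fx, tmp)
  expect_identical(readBin(tmp, "raw", file.size(tmp)),
                   readBin(shipped, "raw", file.size(shipped)))
  back <- read_cohort(shipped)
  expect_equal(as.data.frame(back), as.data.frame(fx))
  fr <- flag_rates(fx, 19)
  expect_equal(fr$n_rejected_flagged, 17)
  expect_equal(fr$n_clear_flagged, 7)
  cs <- crossing_stats(fx, 19)
  expect_equal(cs$n, 17)
  expect_equal(cs$mean, 90 / 17)
  expect_equal(c(cs$min, cs$max), c(2, 11))
  # the per-month pattern of last pre-rejection visits: 5/7/6/3 at 1/3/6/9
  rej <- dplyr::distinct(tibble::as_tibble(fx)[fx$group == "rejected",
                                               c("patient_id", "rejection_month")])
  expect_equal(unname(table(rej$rejection_month)[c("3", "6", "9", "12")]),
               table(c(rep(3, 5), rep(6, 7), rep(9, 6), rep(12, 3))) |> unname())
})

test_that("per-visit phantom volumes recover the tabulated thicknesses", {
  one <- tibble::tibble(patient_id = "P01", group = "clear", age_years = 60,
                        transplant_type = "PK", visit_month = 3,
                        endmt_um = 19, cct_um = 610,
                        rejection_month = NA_real_, censor_month = 12)
  vols <- cohort_to_volumes(one, speckle_sigma = 0.15, n_scans = 4L, width = 256L)
  expect_equal(nrow(vols), 1)
  # flagged visit (>= 19 um) is rendered with an excrescence
  expect_false(is.null(vols$truth[[1]]$spec$excrescences))
  m <- measure_visit(vols$volume[[1]])
  expect_gte(m$endmt_um, 18)
  expect_lte(m$endmt_um, 20)
  expect_lt(abs(m$cct_um - vols$truth[[1]]$cct_central), 3)
  # empty cohort gives an empty volume set
  expect_equal(nrow(cohort_to_volumes(one[0, ])), 0)
  # unflagged visit carries no excrescence
  one$endmt_um <- 14
  v2 <- cohort_to_volumes(one, n_scans = 4L, width = 256L)
  expect_null(v2$truth[[1]]$spec$excrescences)
})
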