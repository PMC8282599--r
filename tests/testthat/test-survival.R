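test_that("counting-process construction follows the carry-forward rules", {
  hc <- hand_cohort()
  rows <- to_counting_process(hc, 19)
  # clear graft B never crosses: one censored row over the whole follow-up
  b <- rows[rows$patient_id == "B", ]
  expect_equal(as.numeric(b[1, c("t_start", "t_stop", "event", "x_threshold")]),
               c(0, 12, 0, 0))
  # graft A crosses at month 3 and rejects at month 9
  a <- rows[rows$patient_id == "A", ]
  expect_equal(a$t_start, c(0, 3))
  expect_equal(a$t_stop, c(3, 9))
  expect_equal(a$event, c(0L, 1L))
  expect_equal(a$x_threshold, c(0L, 1L))
  # graft C never crosses before rejection
  cc <- rows[rows$patient_id == "C", ]
  expect_equal(as.numeric(cc[1, c("t_start", "t_stop", "event", "x_threshold")]),
               c(0, 6, 1, 0))
  expect_error(to_counting_process(hc, -1), "positive")
  bad <- hc; bad$visit_month[2] <- 1
  expect_error(to_counting_process(bad, 19), "non-monotone")
})

test_that("counting-process intervals partition each patient's follow-up", {
  fx <- fixture_default()
  for (cp in c(17, 19, 21)) {
    rows <- to_counting_process(fx, cp)
    by_pat <- split(rows, rows$patient_id)
    for (p in by_pat) {
      p <- p[order(p$t_start), ]
      expect_equal(p$t_start[1], 0)
      if (nrow(p) > 1) expect_equal(p$t_start[-1], p$t_stop[-nrow(p)])
      expect_true(all(p$event[-nrow(p)] == 0))  # event only terminal
    }
    # total duration equals follow-up time over the whole fixture
    fu <- tibble::as_tibble(fx) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(end = ifelse(.data$group[1] == "rejected",
                                    .data$rejection_month[1], .data$censor_month[1]))
    expect_equal(sum(rows$t_stop - rows$t_start), sum(fu$end))
  }
})

test_that("Cox estimates match the brute-force Breslow partial-likelihood oracle", {
  toys <- list(
    tibble::tibble(patient_id = sprintf("T%d", 1:6), t_start = 0, t_stop = 1:6,
                   event = c(1, 1, 1, 1, 0, 0), x_threshold = c(1, 0, 1, 0, 1, 0)),
    # tied event times exercise the Breslow approximation
    tibble::tibble(patient_id = sprintf("U%d", 1:8), t_start = 0,
                   t_stop = c(2, 2, 3, 3, 5, 6, 7, 8),
                   event = c(1, 1, 1, 0, 1, 1, 0, 0),
                   x_threshold = c(1, 1, 0, 1, 1, 0, 0, 1)),
    # counting-process rows with a covariate switch
    tibble::tibble(patient_id = c("V1", "V1", "V2", "V3", "V3", "V4", "V5"),
                   t_start = c(0, 3, 0, 0, 2, 0, 0),
                   t_stop = c(3, 8, 6, 2, 9, 5, 10),
                   event = c(0, 1, 1, 0, 1, 1, 0),
                   x_threshold = c(0, 1, 0, 0, 1, 0, 0)))
  for (toy in toys) {
    fit <- fit_cox_td(toy)
    expect_equal(fit$status, "ok")
    beta_hat <- tidy(fit)$estimate[tidy(fit)$term == "x_threshold"]
    expect_lt(abs(beta_hat - breslow_grid_beta(toy)), 1e-3)
  }
})

test_that("degenerate exposure patterns are reported as non-identifiable", {
  toy <- tibble::tibble(patient_id = sprintf("T%d", 1:6), t_start = 0, t_stop = 1:6,
                        event = c(1, 1, 1, 1, 0, 0), x_threshold = 1L)
  f <- fit_cox_td(toy)
  expect_equal(f$status, "non_identifiable")
  expect_true(is.na(tidy(f)$estimate[1]))
  # all events inside one stratum: monotone likelihood
  toy2 <- tibble::tibble(patient_id = sprintf("T%d", 1:8), t_start = 0,
                         t_stop = c(1, 2, 3, 4, 9, 10, 11, 12),
                         event = c(1, 1, 1, 1, 0, 0, 0, 0),
                         x_threshold = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(fit_cox_td(toy2)$status, "non_identifiable")
  expect_error(fit_cox_td(toy[1:2, ] |> dplyr::mutate(event = c(1, 0))), "2 events")
})

test_that("the cutpoint sweep mirrors the fixture and is exposure-monotone", {
  fx <- fixture_default()
  sw <- sweep_cutpoints(fx)
  expect_equal(nrow(sw), 5)
  expect_equal(sw$cutpoint_um, 17:21)
  expect_true(all(sw$status == "ok"))
  # person-time at X = 1 is non-increasing in the cutpoint
  expect_true(all(diff(sw$person_time_exposed) <= 0))
  # a cutpoint below every observation leaves no contrast
  sw0 <- sweep_cutpoints(fx, cutpoints = c(1, 19))
  expect_equal(sw0$status[1], "non_identifiable")
  expect_equal(sw0$status[2], "ok")
})

test_that("flag rates and crossing stats match manual enumeration", {
  hc <- hand_cohort()
  fr <- flag_rates(hc, 19)
  expect_equal(fr$rejected_flagged, 1 / 2)  # A crosses, C does not
  expect_equal(fr$clear_flagged, 0)
  expect_equal(flag_rates(hc, 1e6)$rejected_flagged, 0)
  expect_error(flag_rates(hc[hc$group == "clear", ], 19), "non-empty")
  cs <- crossing_stats(hc, 19)
  expect_equal(cs$n, 1)
  expect_equal(c(cs$mean, cs$min, cs$max), c(6, 6, 6))
  expect_error(crossing_stats(hc, 1e6), "no flagged rejections")
  # fixture lead-time mean equals the independent arithmetic recomputation
  fx <- fixture_default()
  cf <- crossing_stats(fx, 19)
  expect_equal(cf$mean, sum(tidy(cf)$lead_months) / 17)
})

test_that("stepwise selection retains the threshold and screens candidates", {
  fx <- fixture_default()
  base <- fit_cox_td(to_counting_process(fx, 19))
  none <- forward_stepwise(fx, 19, candidates = character())
  expect_equal(tidy(none)$estimate, tidy(base)$estimate)
  expect_equal(none$selected, character(0))
  # a strong simulated age effect (log-HR -0.1/year) enters in most cohorts
  entered <- vapply(1:20, function(s) {
    co_age <- simulate_cohort(cohort_config(age_loghr = -0.1, seed = s))
    st <- forward_stepwise(co_age, 19, candidates = c("age_years"))
    expect_true("x_threshold" %in% tidy(st)$term)
    "age_years" %in% st$selected
  }, logical(1))
  expect_gte(mean(entered), 0.7)
})

test_that("a pure-noise covariate enters in at most 10% of seeds", {
  entered <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_config(seed = s))
    noise <- withr::with_seed(s + 5000L, {
      ids <- unique(co$patient_id)
      setNames(rnorm(length(ids)), ids)
    })
    co$noise_cov <- noise[co$patient_id]
    st <- forward_stepwise(co, 19, candidates = "noise_cov")
    "noise_cov" %in% st$selected
  }, logical(1))
  expect_lte(mean(entered), 0.10)
})
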