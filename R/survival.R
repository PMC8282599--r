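#' Expand a cohort into counting-process rows for a threshold covariate
#'
#' Builds `(t_start, t_stop]` intervals per patient with the time-dependent
#' indicator `x_threshold(t)`, which switches to 1 at the first visit month
#' whose En/DMT is at or above `cutpoint` and is carried forward thereafter
#' (last observation carried forward between visits). Follow-up ends with an
#' event at the rejection month for rejected grafts and with censoring at the
#' last visit (or recorded censoring month) for clear grafts. Only
#' pre-rejection measurements enter the predictor series.
#'
#' @param cohort a `cohort_table`.
#' @param cutpoint En/DMT threshold, um (> 0).
#' @param covariates patient-level covariate columns to carry along (e.g.
#'   `"age_years"`, `"transplant_type"`).
#' @return Tibble with columns `patient_id`, `t_start`, `t_stop`, `event`,
#'   `x_threshold` and any requested covariates. Patients without visits are
#'   excluded with a warning; non-monotone visit months are an error.
#' @export
to_counting_process <- function(cohort, cutpoint, covariates = character()) {
  if (cutpoint <= 0) abort("`cutpoint` must be positive")
  cohort <- tibble::as_tibble(cohort)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    abort(paste0("covariate column(s) not in cohort: ", paste(miss, collapse = ", ")))
  rows <- list()
  dropped <- character(0)
  for (pid in unique(cohort$patient_id)) {
    p <- cohort[cohort$patient_id == pid, ]
    p <- p[order(p$visit_month), ]
    if (any(duplicated(p$visit_month)) || any(diff(p$visit_month) <= 0))
      abort(paste0("non-monotone visit months for patient ", pid))
    rejected <- p$group[1] == "rejected"
    if (rejected && !is.na(p$rejection_month[1]))
      p <- p[p$visit_month < p$rejection_month[1], ]
    if (nrow(p) == 0) { dropped <- c(dropped, pid); next }
    end <- if (rejected) p$rejection_month[1] else {
      if (!is.na(p$censor_month[1])) max(p$censor_month[1], max(p$visit_month))
      else max(p$visit_month)
    }
    ev <- as.integer(rejected)
    crossed <- which(p$endmt_um >= cutpoint)
    cross_m <- if (length(crossed)) p$visit_month[crossed[1]] else NA_real_
    cov <- p[1, covariates, drop = FALSE]
    if (is.na(cross_m) || cross_m >= end) {
      seg <- tibble::tibble(patient_id = pid, t_start = 0, t_stop = end,
                            event = ev, x_threshold = 0L)
    } else {
      seg <- tibble::tibble(patient_id = pid,
                            t_start = c(0, cross_m), t_stop = c(cross_m, end),
                            event = c(0L, ev), x_threshold = c(0L, 1L))
    }
    if (length(covariates))
      seg <- dplyr::bind_cols(seg, cov[rep(1, nrow(seg)), , drop = FALSE])
    rows[[pid]] <- seg
  }
  if (length(dropped))
    warn(paste0("excluded patient(s) without usable visits: ",
                paste(dropped, collapse = ", ")))
  if (!length(rows)) abort("no patients with usable visits")
  dplyr::bind_rows(rows)
}

#' Time-dependent-covariate Cox model on counting-process data
#'
#' Maximises the Cox partial likelihood over `(t_start, t_stop]` intervals
#' with Breslow tie handling (Efron available as an option), the threshold
#' indicator as the exposure of interest and optional baseline covariates.
#' Wald 95% confidence intervals are `exp(beta +/- 1.96 se)`. When the
#' partial likelihood is monotone in the threshold coefficient (all events in
#' one covariate stratum, or no covariate contrast), the fit reports an
#' explicit non-identifiable result instead of a spuriously large estimate.
#'
#' @param rows counting-process tibble (see [to_counting_process()]).
#' @param covariates additional model terms (column names in `rows`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_td_fit` with elements `status`
#'   (`"ok"`/`"non_identifiable"`), `coefficients` tibble (term, estimate =
#'   log HR, std.error, statistic, p.value, hazard.ratio, conf.low,
#'   conf.high), `n`, `n_events`, `ties` and the underlying
#'   [survival::coxph()] model. Supports [tidy()] and [glance()].
#' @export
fit_cox_td <- function(rows, covariates = character(), ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  rows <- tibble::as_tibble(rows)
  if (any(rows$t_start >= rows$t_stop)) abort("intervals must satisfy t_start < t_stop")
  n_events <- sum(rows$event)
  if (n_events < 2) abort("need at least 2 events")
  n_sub <- length(unique(rows$patient_id))

  non_ident <- function(reason) {
    structure(list(status = "non_identifiable", reason = reason,
                   coefficients = tibble::tibble(
                     term = "x_threshold", estimate = NA_real_,
                     std.error = NA_real_, statistic = NA_real_,
                     p.value = NA_real_, hazard.ratio = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_),
                   n = n_sub, n_events = n_events, ties = ties, model = NULL),
              class = "cox_td_fit")
  }
  if (length(unique(rows$x_threshold)) < 2)
    return(non_ident("threshold covariate has no contrast"))
  ev_x <- rows$x_threshold[rows$event == 1]
  if (length(unique(ev_x)) < 2 && !length(covariates)) {
    # all events in one stratum of the binary exposure: monotone likelihood
    return(non_ident("all events occur in one threshold stratum"))
  }

  fml <- stats::as.formula(paste(
    "survival::Surv(t_start, t_stop, event) ~ x_threshold",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = rows, ties = ties),
    warning = function(w) {
      if (grepl("infinite|Loglik converged", conditionMessage(w))) diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(is.na(coef(fit)))) abort("singular information matrix")
  if (diverged || any(abs(coef(fit)) > 15))
    return(non_ident("monotone partial likelihood (divergent coefficient)"))

  s <- summary(fit)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = unname(2 * stats::pnorm(-abs(est / se))),
    hazard.ratio = exp(unname(est)),
    conf.low = exp(unname(est - qnorm(0.975) * se)),
    conf.high = exp(unname(est + qnorm(0.975) * se)))
  structure(list(status = "ok", reason = NULL, coefficients = coefs,
                 n = n_sub, n_events = n_events, ties = ties, model = fit,
                 converged = is.null(fit$info), loglik = fit$loglik),
            class = "cox_td_fit")
}

#' @export
print.cox_td_fit <- function(x, ...) {
  cat(sprintf("<cox_td_fit> %s ties, %d subjects, %d events, status: %s\n",
              x$ties, x$n, x$n_events, x$status))
  if (x$status == "ok") print(as.data.frame(x$coefficients), digits = 4)
  else cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Hazard-ratio sweep over En/DMT cutpoints
#'
#' Composes [to_counting_process()] and [fit_cox_td()] for each cutpoint,
#' mirroring the published cutpoint table: one row per threshold with the
#' hazard ratio of rejection after the graft's En/DMT first reaches that
#' threshold, its Wald 95% CI and p-value. Fit failures are recorded in the
#' row and the sweep continues.
#'
#' @param cohort a `cohort_table`.
#' @param cutpoints distinct positive thresholds, um (default 17-21).
#' @param covariates optional baseline covariates.
#' @param ties tie handling passed to [fit_cox_td()].
#' @return A `sweep_table` tibble: `cutpoint_um`, `hazard.ratio`, `conf.low`,
#'   `conf.high`, `p.value`, `n_events`, `person_time_exposed` (months with
#'   the indicator at 1) and `status`.
#' @export
sweep_cutpoints <- function(cohort, cutpoints = 17:21, covariates = character(),
                            ties = "breslow") {
  if (any(cutpoints <= 0) || anyDuplicated(cutpoints))
    abort("`cutpoints` must be positive and distinct")
  rows <- purrr::map_dfr(cutpoints, function(cp) {
    res <- tryCatch({
      cp_rows <- to_counting_process(cohort, cp, covariates)
      fit <- fit_cox_td(cp_rows, covariates = covariates, ties = ties)
      pt1 <- sum((cp_rows$t_stop - cp_rows$t_start)[cp_rows$x_threshold == 1])
      co <- fit$coefficients[fit$coefficients$term == "x_threshold", ]
      tibble::tibble(cutpoint_um = cp, hazard.ratio = co$hazard.ratio,
                     conf.low = co$conf.low, conf.high = co$conf.high,
                     p.value = co$p.value, n_events = fit$n_events,
                     person_time_exposed = pt1, status = fit$status)
    }, error = function(e)
      tibble::tibble(cutpoint_um = cp, hazard.ratio = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     p.value = NA_real_, n_events = NA_integer_,
                     person_time_exposed = NA_real_,
                     status = paste0("error: ", conditionMessage(e))))
    res
  })
  class(rows) <- c("sweep_table", class(rows))
  rows
}

#' Threshold flag rates by outcome group
#'
#' A rejected graft is flagged when any pre-rejection visit has En/DMT at or
#' above the cutpoint; a clear graft when any visit does.
#'
#' @param cohort a `cohort_table`.
#' @param cutpoint threshold, um (> 0).
#' @return One-row tibble: `rejected_flagged`, `clear_flagged` (fractions),
#'   plus the underlying counts.
#' @export
flag_rates <- function(cohort, cutpoint) {
  if (cutpoint <= 0) abort("`cutpoint` must be positive")
  cohort <- tibble::as_tibble(cohort)
  pat <- cohort |>
    dplyr::group_by(.data$patient_id, .data$group) |>
    dplyr::summarise(flagged = any(.data$endmt_um >= cutpoint), .groups = "drop")
  n_rej <- sum(pat$group == "rejected"); n_clr <- sum(pat$group == "clear")
  if (n_rej == 0 || n_clr == 0) abort("both outcome groups must be non-empty")
  tibble::tibble(
    rejected_flagged = sum(pat$flagged[pat$group == "rejected"]) / n_rej,
    clear_flagged = sum(pat$flagged[pat$group == "clear"]) / n_clr,
    n_rejected_flagged = sum(pat$flagged[pat$group == "rejected"]),
    n_rejected = n_rej,
    n_clear_flagged = sum(pat$flagged[pat$group == "clear"]),
    n_clear = n_clr)
}

#' Lead times from first threshold crossing to rejection
#'
#' For every rejected graft whose En/DMT reaches the cutpoint before
#' rejection, the lead time is `rejection month - first crossing visit
#' month`.
#'
#' @param cohort a `cohort_table`.
#' @param cutpoint threshold, um.
#' @return A list of class `crossing_stats`: `lead_times` tibble
#'   (`patient_id`, `crossing_month`, `rejection_month`, `lead_months`) and
#'   summaries `mean`, `min`, `max`, `n`. Errors with "no flagged rejections"
#'   when no rejected graft crosses.
#' @export
crossing_stats <- function(cohort, cutpoint) {
  cohort <- tibble::as_tibble(cohort)
  rej <- cohort[cohort$group == "rejected", ]
  rej <- rej[rej$endmt_um >= cutpoint, ]
  if (nrow(rej) == 0) abort("no flagged rejections")
  lt <- rej |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(crossing_month = min(.data$visit_month),
                     rejection_month = .data$rejection_month[1],
                     .groups = "drop") |>
    dplyr::mutate(lead_months = .data$rejection_month - .data$crossing_month)
  if (nrow(lt) == 0) abort("no flagged rejections")
  if (any(lt$lead_months <= 0)) abort("crossing at or after rejection: invalid cohort")
  structure(list(lead_times = lt, mean = mean(lt$lead_months),
                 min = min(lt$lead_months), max = max(lt$lead_months),
                 n = nrow(lt)),
            class = "crossing_stats")
}

#' @export
print.crossing_stats <- function(x, ...) {
  cat(sprintf("<crossing_stats> n = %d, lead time mean %.2f months (range %g-%g)\n",
              x$n, x$mean, x$min, x$max))
  invisible(x)
}

#' Forward stepwise covariate selection around the threshold model
#'
#' Starts from the time-dependent threshold model and iteratively adds the
#' candidate covariate with the smallest Wald p-value while it is below
#' `alpha`; the threshold covariate itself is always retained. Categorical
#' candidates are tested with a block Wald chi-square across their levels.
#'
#' @param cohort a `cohort_table`.
#' @param cutpoint threshold, um.
#' @param candidates candidate covariate column names.
#' @param alpha entry significance level.
#' @param ties tie handling.
#' @return A `cox_td_fit` for the final model, with an extra element
#'   `selected` listing the covariates that entered, in order.
#' @export
forward_stepwise <- function(cohort, cutpoint, candidates = character(),
                             alpha = 0.05, ties = "breslow") {
  rows <- to_counting_process(cohort, cutpoint, covariates = candidates)
  selected <- character(0)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    pvals <- vapply(remaining, function(cand) {
      f <- tryCatch(fit_cox_td(rows, covariates = c(selected, cand), ties = ties),
                    error = function(e) NULL)
      if (is.null(f) || f$status != "ok") return(NA_real_)
      wald_term_p(f$model, cand)
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- which.min(pvals)
    if (is.na(pvals[best]) || pvals[best] >= alpha) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  out <- fit_cox_td(rows, covariates = selected, ties = ties)
  out$selected <- selected
  out
}

wald_term_p <- function(model, term) {
  asg <- model$assign
  labs <- attr(stats::terms(model), "term.labels")
  k <- which(labs == term)
  if (!length(k)) return(NA_real_)
  idx <- if (is.list(asg)) asg[[k]] else which(asg == k)
  b <- coef(model)[idx]
  V <- vcov(model)[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  pchisq(stat, df = length(idx), lower.tail = FALSE)
}
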