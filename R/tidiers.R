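#' Tidy a time-dependent Cox fit
#'
#' @param x a `cox_td_fit`.
#' @param ... unused.
#' @return Tibble of per-term estimates on the log-hazard scale with hazard
#'   ratios and Wald confidence bounds.
#' @exportS3Method generics::tidy
#' @export
tidy.cox_td_fit <- function(x, ...) x$coefficients

#' @rdname tidy.cox_td_fit
#' @exportS3Method generics::glance
#' @export
glance.cox_td_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, ties = x$ties,
                 status = x$status,
                 loglik = if (!is.null(x$loglik)) x$loglik[length(x$loglik)] else NA_real_)
}

#' Tidy a repeated-measures trend fit
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return Tibble of fixed-effect estimates with Satterthwaite p-values.
#' @exportS3Method generics::tidy
#' @export
tidy.trend_fit <- function(x, ...) x$fixed

#' @rdname tidy.trend_fit
#' @exportS3Method generics::glance
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(measure = x$measure,
                 interaction_estimate = x$interaction$estimate,
                 interaction_p = x$interaction$p.value,
                 random_intercept_var = x$random_intercept_var,
                 n_obs = stats::nobs(x$model))
}

#' Tidy crossing-interval statistics
#'
#' @param x a `crossing_stats`.
#' @param ... unused.
#' @return Per-patient lead times.
#' @exportS3Method generics::tidy
#' @export
tidy.crossing_stats <- function(x, ...) x$lead_times

#' @rdname tidy.crossing_stats
#' @exportS3Method generics::glance
#' @export
glance.crossing_stats <- function(x, ...) {
  tibble::tibble(n = x$n, mean_lead_months = x$mean,
                 min_lead_months = x$min, max_lead_months = x$max)
}
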