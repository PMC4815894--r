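#' Survival records
#'
#' Validates and assembles the survival input used throughout the package:
#' one row per sample with a follow-up time in months and an event indicator
#' (1 = the endpoint occurred, 0 = censored at that time). Two endpoints are
#' recognised: biochemical recurrence (`"BCR"`, post-treatment PSA rise) and
#' clinical recurrence (`"CR"`, clinically manifest progression).
#'
#' @param sample_id character vector of unique ids.
#' @param time_months follow-up time, finite and >= 0.
#' @param event event indicator: logical or 0/1.
#' @param endpoint `"BCR"` or `"CR"` (recycled).
#' @return a `data.frame` of class `survival_records`.
#' @export
survival_records <- function(sample_id, time_months, event,
                             endpoint = "BCR") {
  if (length(sample_id) == 0L) stop_validation("no survival records supplied")
  if (anyDuplicated(sample_id)) stop_validation("sample ids must be unique")
  assert_finite(time_months, "time_months")
  if (any(time_months < 0)) stop_validation("time_months must be >= 0")
  event <- as_binary_labels(event)
  if (!all(endpoint %in% c("BCR", "CR"))) {
    stop_validation("endpoint must be 'BCR' or 'CR'")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    time_months = as.numeric(time_months),
                    event = event,
                    endpoint = rep_len(endpoint, length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_records", "data.frame")
  out
}

as_survival_records <- function(records) {
  if (inherits(records, "survival_records")) return(records)
  need <- c("sample_id", "time_months", "event")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_validation(
      "records must have columns sample_id, time_months, event")
  }
  survival_records(records$sample_id, records$time_months, records$event,
                   if ("endpoint" %in% names(records)) records$endpoint
                   else "BCR")
}

#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator (via [survival::survfit()]) and returns
#' the step function together with the median survival time, defined as the
#' earliest event time at which the survival estimate drops to 0.5 or below
#' (`NA` if the curve never reaches 0.5). With no censoring the estimate
#' coincides exactly with the empirical survival function.
#'
#' @param records a [survival_records()] data frame (or coercible).
#' @return a `km_curve` list: `time` (ascending event times), `surv`,
#'   `n_risk`, `n_event`, `n_censor`, `median`, `n`.
#' @export
km_fit <- function(records) {
  records <- as_survival_records(records)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  tim <- fit$time[keep]
  s <- fit$surv[keep]
  med <- if (any(s <= 0.5)) tim[which(s <= 0.5)[1L]] else NA_real_
  structure(list(time = tim, surv = s,
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 n_censor = sum(records$event == 0L),
                 median = med, n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: n = %d, %d events, %d censored, median = %s months\n",
              x$n, sum(x$n_event), x$n_censor,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test between two groups
#'
#' Standard 1-df log-rank chi-square (via [survival::survdiff()]) with a
#' two-sided p-value.
#'
#' @param records a [survival_records()] data frame covering both groups.
#' @param group a two-level factor/character vector aligned with `records`.
#' @return a list: `chisq`, `p_value`, `observed`, `expected` (named by
#'   group level).
#' @export
logrank <- function(records, group) {
  records <- as_survival_records(records)
  group <- as.factor(group)
  if (length(group) != nrow(records)) {
    stop_validation("group must align with records")
  }
  if (nlevels(droplevels(group)) != 2L) {
    stop_validation("exactly two groups required")
  }
  if (sum(records$event) == 0L) {
    fs_stop("no events in either group; log-rank test undefined",
            "fusionstrat_undefined_test_error")
  }
  d <- data.frame(time_months = records$time_months, event = records$event,
                  group = droplevels(group))
  sd <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = d)
  structure(list(chisq = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 observed = stats::setNames(sd$obs, levels(d$group)),
                 expected = stats::setNames(sd$exp, levels(d$group))),
            class = "logrank_test")
}

#' Hazard ratio between two survival groups
#'
#' Estimates the hazard ratio of the second group level relative to the first
#' (reference). The default `"oe"` estimator is
#' \eqn{HR = (O_2/E_2)/(O_1/E_1)} from the log-rank observed/expected event
#' counts, with a log-scale (Tsiatis-style) 95% CI using
#' \eqn{se(\log HR) = \sqrt{1/E_1 + 1/E_2}} — the statistic that KM-module
#' reports conventionally print alongside the log-rank test. Note the O/E
#' ratio is attenuated toward 1 for strong effects (a fixed bias that does
#' not vanish with sample size); `estimator = "cox"` fits a single-covariate
#' Cox model instead, which is consistent, and serves as the cross-check
#' when an unattenuated estimate matters. With group levels ordered
#' low-expression then high-expression, HR < 1 means the high-expression
#' group suffers fewer events than expected — a protective marker.
#'
#' @inheritParams logrank
#' @param conf_level CI coverage (default 0.95).
#' @param estimator `"oe"` (log-rank observed/expected ratio, default) or
#'   `"cox"` (Cox partial-likelihood estimate).
#' @return a `survival_comparison` list: `hr`, `ci_low`, `ci_high`, `chisq`,
#'   `p_value`, `groups` (level names, reference first), `observed`,
#'   `expected`, `curves` (per-group [km_fit()] results), `medians`,
#'   `estimator`.
#' @export
hazard_ratio <- function(records, group, conf_level = 0.95,
                         estimator = c("oe", "cox")) {
  estimator <- match.arg(estimator)
  records <- as_survival_records(records)
  group <- droplevels(as.factor(group))
  lr <- logrank(records, group)
  O <- lr$observed
  E <- lr$expected
  if (any(E <= 0)) {
    fs_stop(sprintf("zero expected events in group '%s'; HR undefined",
                    names(E)[E <= 0][1L]),
            "fusionstrat_undefined_hr_error")
  }
  if (any(O == 0)) {
    warning("a group has zero observed events; HR estimate is degenerate")
  }
  if (estimator == "oe") {
    hr <- (O[2L] / E[2L]) / (O[1L] / E[1L])
    se_log <- sqrt(1 / E[1L] + 1 / E[2L])
  } else {
    d <- data.frame(time_months = records$time_months,
                    event = records$event, group = group)
    cx <- survival::coxph(
      survival::Surv(time_months, event) ~ group, data = d)
    hr <- exp(unname(stats::coef(cx)[1L]))
    se_log <- sqrt(unname(stats::vcov(cx)[1L, 1L]))
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  curves <- lapply(levels(group), function(g) {
    km_fit(records[group == g, , drop = FALSE])
  })
  names(curves) <- levels(group)
  structure(list(hr = unname(hr),
                 ci_low = unname(hr * exp(-zq * se_log)),
                 ci_high = unname(hr * exp(zq * se_log)),
                 chisq = lr$chisq, p_value = lr$p_value,
                 groups = levels(group), observed = O, expected = E,
                 curves = curves,
                 medians = vapply(curves, `[[`, numeric(1), "median"),
                 estimator = estimator),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("HR (%s vs %s) = %.3f (95%% CI %.3f-%.3f); log-rank p = %.3g\n",
              x$groups[2L], x$groups[1L], x$hr, x$ci_low, x$ci_high,
              x$p_value))
  meds <- vapply(x$medians, function(m) {
    if (is.na(m)) "NR" else format(m)
  }, character(1))
  cat(sprintf("  median survival: %s = %s, %s = %s months\n",
              x$groups[1L], meds[1L], x$groups[2L], meds[2L]))
  invisible(x)
}

#' Stratify survival by an expression cutoff
#'
#' Splits samples at a normalized-expression cutoff — low group strictly
#' below the cutoff, high group the remainder (a sample exactly at the cutoff
#' is high) — and compares the two survival curves. The HR is reported for
#' high vs low, so HR < 1 means high expression is protective.
#'
#' @param expression named numeric vector of normalized expression,
#'   names = sample ids.
#' @param cutoff finite expression cutoff.
#' @param records a [survival_records()] data frame; joined to `expression`
#'   on `sample_id`.
#' @return a list: `low` / `high` (sample id vectors) and `comparison`
#'   (a [hazard_ratio()] result).
#' @export
stratify_by_cutoff <- function(expression, cutoff, records) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop_validation("cutoff must be a single finite number")
  }
  if (is.null(names(expression))) {
    stop_validation("expression must be named by sample id")
  }
  records <- as_survival_records(records)
  common <- intersect(names(expression), records$sample_id)
  if (length(common) == 0L) {
    stop_validation("no samples shared between expression and records")
  }
  expr <- expression[common]
  rec <- records[match(common, records$sample_id), , drop = FALSE]
  grp <- factor(ifelse(expr < cutoff, "low", "high"),
                levels = c("low", "high"))
  if (any(tabulate(grp, 2L) == 0L)) {
    stop_degenerate(sprintf(
      "cutoff %.4g leaves an empty stratum (%d low, %d high)",
      cutoff, sum(grp == "low"), sum(grp == "high")))
  }
  list(low = common[grp == "low"], high = common[grp == "high"],
       comparison = hazard_ratio(rec, grp))
}

#' Dichotomize time to recurrence at a horizon
#'
#' Classifies each sample as `early` (event before the horizon), `late`
#' (event at or after the horizon — the boundary goes to `late`) or
#' `no_event` (censored, whatever the time). Default horizon 24 months.
#'
#' @param records a [survival_records()] data frame.
#' @param horizon months (default 24).
#' @return factor with levels `early`, `late`, `no_event`, named by sample id.
#' @export
dichotomize_recurrence <- function(records, horizon = 24) {
  records <- as_survival_records(records)
  cat_ <- ifelse(records$event == 1L,
                 ifelse(records$time_months < horizon, "early", "late"),
                 "no_event")
  stats::setNames(factor(cat_, levels = c("early", "late", "no_event")),
                  records$sample_id)
}

#' Restrict to samples with defined status at a follow-up horizon
#'
#' For with-vs-without-event comparisons inside a fixed follow-up window
#' (default 5 years), a sample's group is defined only if it either had the
#' event within the window, or is known event-free through the whole window.
#' Samples censored before the horizon without an event are dropped (their
#' within-window status is unknown); the number dropped is reported via
#' `message()`.
#'
#' @param records a [survival_records()] data frame.
#' @param horizon months (default 60).
#' @return the eligible subset, with an added `followup_group` column
#'   (`"event"` / `"no_event"`).
#' @export
filter_followup <- function(records, horizon = 60) {
  records <- as_survival_records(records)
  is_event <- records$event == 1L & records$time_months <= horizon
  is_free <- records$time_months >= horizon & !is_event
  keep <- is_event | is_free
  if (any(!keep)) {
    message(sprintf(
      "filter_followup: dropped %d sample(s) censored before %g months",
      sum(!keep), horizon))
  }
  out <- records[keep, , drop = FALSE]
  out$followup_group <- ifelse(is_event[keep], "event", "no_event")
  out
}
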