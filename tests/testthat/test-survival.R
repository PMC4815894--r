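make_records <- function(time, event, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(time))
  survival_records(ids, time, event)
}

test_that("product-limit estimate equals empirical survival when uncensored", {
  km <- km_fit(make_records(c(1, 2, 3, 4), c(1, 1, 1, 1)))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  set.seed(171)
  for (i in 1:10) {
    times <- round(rexp(sample(5:30, 1), 0.1), 3)
    km <- km_fit(make_records(times, rep(1, length(times))))
    for (k in seq_along(km$time)) {
      expect_equal(km$surv[k], oracle_empirical_surv(times, km$time[k]))
    }
  }
})

test_that("the hand-computed mixed-censoring fixture matches step for step", {
  # (1+, 2, 3, 3+, 5, 6): risk sets 5, 4, 2, 1 at the four event times
  km <- km_fit(make_records(c(1, 2, 3, 3, 5, 6), c(0, 1, 1, 0, 1, 1)))
  expect_equal(km$time, c(2, 3, 5, 6))
  expect_equal(km$surv, c(0.8, 0.6, 0.3, 0))
  expect_equal(km$n_risk, c(5, 4, 2, 1))
  expect_equal(km$median, 5)  # earliest time with survival <= 0.5
})

test_that("fully censored data give a flat curve with undefined median", {
  km <- km_fit(make_records(c(10, 20, 30), c(0, 0, 0)))
  expect_length(km$time, 0)
  expect_true(is.na(km$median))
  expect_equal(km$n_censor, 3L)
  expect_error(km_fit(make_records(numeric(0), integer(0))),
               class = "fusionstrat_validation_error")
  expect_error(survival_records("a", -1, 1),
               class = "fusionstrat_validation_error")
})

test_that("log-rank matches a first-principles computation", {
  set.seed(181)
  for (i in 1:10) {
    n <- sample(20:40, 1)
    time <- round(rexp(n, 0.05), 2)
    event <- rbinom(n, 1, 0.8)
    group <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    lr <- logrank(make_records(time, event), group)
    expect_equal(lr$chisq, oracle_logrank_chisq(time, event, group),
                 tolerance = 1e-8)
  }
})

test_that("log-rank is symmetric and null on identical groups", {
  time <- rep(c(5, 10, 15, 20), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c("a", "b"), each = 4)
  lr <- logrank(make_records(time, event), group)
  expect_lt(lr$chisq, 1e-10)
  expect_gt(lr$p_value, 0.999)
  swapped <- logrank(make_records(time, event),
                     rep(c("b", "a"), each = 4))
  expect_equal(lr$chisq, swapped$chisq)
  expect_error(logrank(make_records(c(1, 2), c(0, 0)), c("a", "b")),
               class = "fusionstrat_undefined_test_error")
})

test_that("hazard ratio is the O/E ratio with reciprocal symmetry", {
  set.seed(191)
  time <- c(rexp(60, 0.1), rexp(60, 0.03))
  event <- rep(1, 120)
  group <- factor(rep(c("low", "high"), each = 60),
                  levels = c("low", "high"))
  hr <- hazard_ratio(make_records(time, event), group)
  # high group has a ~3x lower hazard: HR(high vs low) well under 1
  expect_lt(hr$hr, 1)
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)
  flipped <- hazard_ratio(make_records(time, event),
                          factor(group, levels = c("high", "low")))
  expect_equal(hr$hr, 1 / flipped$hr, tolerance = 1e-10)
  # identical groups: HR near 1
  t2 <- rep(c(3, 6, 9, 12, 15), 2)
  hr1 <- hazard_ratio(make_records(t2, rep(1, 10)),
                      rep(c("low", "high"), each = 5))
  expect_equal(hr1$hr, 1, tolerance = 1e-8)
})

test_that("the Cox estimator is an unattenuated cross-check of the O/E ratio", {
  set.seed(195)
  time <- c(rexp(300, 0.08), rexp(300, 0.04))  # true HR 0.5, moderate
  grp <- factor(rep(c("low", "high"), each = 300), levels = c("low", "high"))
  rec <- make_records(time, rep(1, 600))
  oe <- hazard_ratio(rec, grp)
  cox <- hazard_ratio(rec, grp, estimator = "cox")
  expect_identical(oe$estimator, "oe")
  expect_identical(cox$estimator, "cox")
  # both land near the truth for a moderate effect
  expect_equal(oe$hr, 0.5, tolerance = 0.25)
  expect_equal(cox$hr, 0.5, tolerance = 0.25)
  # O/E sits between the Cox estimate and 1 (attenuation toward the null)
  expect_gte(oe$hr, cox$hr - 1e-9)
})

test_that("hazard ratio recovers a planted 0.3 effect at n=200/arm", {
  set.seed(201)
  hits <- 0L
  for (s in 1:10) {
    time <- c(rexp(200, 0.1), rexp(200, 0.03))
    group <- factor(rep(c("low", "high"), each = 400 / 2),
                    levels = c("low", "high"))
    hr <- hazard_ratio(make_records(time, rep(1, 400)), group)
    if (hr$hr >= 0.2 && hr$hr <= 0.45) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("cutoff stratification uses a strict lower bound for the low group", {
  expr <- c(a = 1, b = 2, c = 3, d = 4)
  rec <- make_records(c(5, 10, 15, 20), c(1, 1, 1, 0),
                      ids = c("a", "b", "c", "d"))
  s <- stratify_by_cutoff(expr, 3, rec)
  expect_setequal(s$low, c("a", "b"))
  expect_setequal(s$high, c("c", "d"))  # sample exactly at the cutoff: high
  expect_error(stratify_by_cutoff(expr, 0.5, rec),
               class = "fusionstrat_degenerate_error")
  expect_error(stratify_by_cutoff(unname(expr), 3, rec),
               class = "fusionstrat_validation_error")
})

test_that("protective expression yields shorter times in the low group", {
  p <- cohort_params(n_samples = 400, seed = 211, log_hr_per_unit = -0.8,
                     censor_uniform_max = 1e6, admin_horizon = 1e6)
  co <- generate_cohort(p)
  expr <- setNames(unclass(co$expression)["PDE4D7", ], co$annotation$sample_id)
  rec <- survival_records(co$annotation$sample_id,
                          co$annotation$time_months, co$annotation$event)
  s <- stratify_by_cutoff(expr, median(expr), rec)
  expect_lt(s$comparison$medians[["low"]], s$comparison$medians[["high"]])
  expect_lt(s$comparison$hr, 1)
})

test_that("recurrence dichotomy splits at 24 months with ties late", {
  rec <- make_records(c(10, 30, 40, 24), c(1, 1, 0, 1))
  d <- dichotomize_recurrence(rec)
  expect_identical(as.character(d),
                   c("early", "late", "no_event", "late"))
  expect_named(d, rec$sample_id)
})

test_that("follow-up filter keeps only samples with defined 5-year status", {
  rec <- make_records(c(20, 70, 30, 70), c(1, 0, 0, 1))
  expect_message(out <- filter_followup(rec), "dropped 1")
  expect_setequal(out$sample_id, c("p01", "p02", "p04"))
  expect_identical(out$followup_group[out$sample_id == "p01"], "event")
  # an event beyond the horizon counts as event-free within the window
  expect_identical(out$followup_group[out$sample_id == "p04"], "no_event")
})
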