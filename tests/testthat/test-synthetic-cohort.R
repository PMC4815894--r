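test_that("identical parameters and seed give byte-identical cohorts", {
  p <- cohort_params(n_samples = 120, seed = 42)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_params(n_samples = 120, seed = 43))
  expect_false(identical(unclass(c1$expression), unclass(c3$expression)))
})

test_that("parameter validation catches degenerate configurations", {
  expect_error(cohort_params(n_samples = 1),
               class = "fusionstrat_invalid_parameter_error")
  expect_error(cohort_params(tissue_mix = c(NAT = 0.5, tumour = 0.6)),
               class = "fusionstrat_invalid_parameter_error")
  expect_error(cohort_params(tissue_mix = c(NAT = 0.2, stroma = 0.8)),
               class = "fusionstrat_config_error")  # no stroma baseline
  expect_error(cohort_params(fusion_prevalence = 1),
               class = "fusionstrat_invalid_parameter_error")
  expect_error(cohort_params(erg_neg_sd = 0),
               class = "fusionstrat_invalid_parameter_error")
})

test_that("class and fusion counts are deterministic", {
  co <- generate_cohort(cohort_params(n_samples = 250, seed = 5))
  tab <- table(co$annotation$tissue)
  expect_identical(as.integer(tab[["NAT"]]), 50L)
  expect_identical(as.integer(tab[["tumour"]]), 200L)
  expect_identical(sum(co$truth$fusion), as.integer(round(0.4 * 200)))
  # fusion only in tumours; Gleason only in tumours
  expect_true(all(co$annotation$tissue[co$truth$fusion] == "tumour"))
  expect_true(all(is.na(co$annotation$gleason_group[
    co$annotation$tissue == "NAT"])))
})

test_that("the noise-free limit plants the fusion effect exactly", {
  p <- cohort_params(n_samples = 200, noise_sd = 0, grade_effect = 0,
                     fusion_effect = 1.0, seed = 7)
  co <- generate_cohort(p)
  pde <- unclass(co$expression)["PDE4D7", ]
  tum <- co$annotation$tissue == "tumour"
  diff <- median(pde[tum & co$truth$fusion]) -
    median(pde[tum & !co$truth$fusion])
  expect_equal(diff, 1.0)
  # 2-fold on the linear scale
  expect_equal(2^diff, 2.0)
})

test_that("planted grade effects are recoverable only where planted", {
  sig_pos <- 0L
  null_neg <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    p <- cohort_params(n_samples = 150, grade_effect = -1, noise_sd = 0.5,
                       seed = 3000 + s)
    co <- generate_cohort(p)
    pde <- unclass(co$expression)["PDE4D7", ]
    ann <- co$annotation
    tum <- ann$tissue == "tumour"
    low <- tum & ann$gleason_group %in% 1:2
    high <- tum & ann$gleason_group %in% 3:4
    fus <- co$truth$fusion
    p_pos <- mann_whitney(pde[low & fus], pde[high & fus])$p_value
    p_neg <- mann_whitney(pde[low & !fus], pde[high & !fus])$p_value
    if (p_pos < 0.05) sig_pos <- sig_pos + 1L
    if (p_neg > 0.05) null_neg <- null_neg + 1L
  }
  expect_gte(sig_pos / n_seeds, 0.9)
  expect_gte(null_neg / n_seeds, 0.8)
})

test_that("a negative expression-hazard link shortens low-expression times", {
  longer <- 0L
  for (s in 1:20) {
    p <- cohort_params(n_samples = 200, seed = 4000 + s,
                       log_hr_per_unit = -0.8,
                       censor_uniform_max = 1e6, admin_horizon = 1e6)
    co <- generate_cohort(p)
    pde <- unclass(co$expression)["PDE4D7", ]
    hi <- pde >= median(pde)
    if (median(co$annotation$time_months[hi]) >
        median(co$annotation$time_months[!hi])) {
      longer <- longer + 1L
    }
  }
  expect_gte(longer, 19L)
})

test_that("a null expression-hazard link leaves group medians equal", {
  diffs <- vapply(1:40, function(s) {
    p <- cohort_params(n_samples = 200, seed = 5000 + s, log_hr_per_unit = 0,
                       censor_uniform_max = 1e6, admin_horizon = 1e6)
    co <- generate_cohort(p)
    pde <- unclass(co$expression)["PDE4D7", ]
    rec <- survival_records(co$annotation$sample_id,
                            co$annotation$time_months, co$annotation$event)
    hi <- pde >= median(pde)
    km_fit(rec[hi, ])$median - km_fit(rec[!hi, ])$median
  }, numeric(1))
  # Monte-Carlo error only: mean difference of KM medians near zero
  expect_lt(abs(mean(diffs)), 2.5)
})

test_that("qPCR plates round-trip the planted expression", {
  planted <- setNames(c(0, 1.5, -2, 3.2), paste0("s", 1:4))
  plate <- generate_qpcr_plate(planted, noise_sd = 0, seed = 9)
  norm <- normalize_qpcr_matrix(plate, c("REF1", "REF2", "REF3"))
  expect_equal(unclass(norm)["PDE4D7", ], planted, tolerance = 1e-12)
  # adding a constant to every Ct of a sample leaves the output unchanged
  shifted <- unclass(plate)
  shifted[, 2] <- shifted[, 2] + 1.7
  em2 <- expression_matrix(shifted, platform = "qpcr", scale = "ct")
  norm2 <- normalize_qpcr_matrix(em2, c("REF1", "REF2", "REF3"))
  expect_equal(unclass(norm2)["PDE4D7", ], planted, tolerance = 1e-12)
  expect_error(generate_qpcr_plate(planted, reference_genes = character(0)),
               class = "fusionstrat_config_error")
})

test_that("noisy qPCR plates still track the planted values", {
  set.seed(221)
  planted <- setNames(rnorm(100, 1, 2), sprintf("s%03d", 1:100))
  plate <- generate_qpcr_plate(planted, noise_sd = 0.1, seed = 10)
  norm <- normalize_qpcr_matrix(plate, c("REF1", "REF2", "REF3"))
  expect_gt(cor(unclass(norm)["PDE4D7", ], planted), 0.99)
})

test_that("cohorts round-trip through the on-disk bundle", {
  co <- generate_cohort(cohort_params(n_samples = 60, seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("expression.tsv", "annotation.tsv", "truth.tsv",
                    "params.yaml"))
  back <- read_expression_matrix(file.path(dir, "expression.tsv"),
                                 platform = "rnaseq", scale = "normalized")
  expect_equal(unclass(back), unclass(co$expression), tolerance = 1e-6)
  prm <- yaml::read_yaml(file.path(dir, "params.yaml"))
  expect_identical(prm$seed, 12L)
  expect_identical(prm$n_samples, 60L)
})
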