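test_that("qPCR normalization is mean(ref Cts) minus Ct of the gene", {
  expect_identical(normalize_qpcr(25, c(24, 26)), 0)
  expect_identical(normalize_qpcr(22, c(24, 26)), 3)
  # vectorized across samples with a ref matrix
  refs <- matrix(c(24, 26, 20, 22), nrow = 2)
  expect_equal(normalize_qpcr(c(25, 19), refs), c(0, 2))
})

test_that("qPCR normalization is invariant under a global Ct shift", {
  set.seed(11)
  for (i in 1:20) {
    goi <- runif(1, 15, 35)
    refs <- runif(sample(1:5, 1), 15, 35)
    shift <- runif(1, -10, 10)
    expect_equal(normalize_qpcr(goi + shift, refs + shift),
                 normalize_qpcr(goi, refs))
  }
})

test_that("qPCR normalization rejects missing references and bad Cts", {
  expect_error(normalize_qpcr(25, numeric(0)),
               class = "fusionstrat_missing_reference_error")
  expect_error(normalize_qpcr(NA_real_, c(24, 26)),
               class = "fusionstrat_validation_error")
  em <- expression_matrix(
    matrix(c(25, 24, 26), 3, 1,
           dimnames = list(c("PDE4D7", "R1", "R2"), "s1")),
    platform = "qpcr", scale = "ct")
  expect_error(normalize_qpcr_matrix(em, character(0)),
               class = "fusionstrat_missing_reference_error")
  expect_error(normalize_qpcr_matrix(em, c("R1", "R9")),
               class = "fusionstrat_config_error")
  norm <- normalize_qpcr_matrix(em, c("R1", "R2"))
  expect_equal(unname(unclass(norm)["PDE4D7", ]), 0)
  expect_identical(attr(norm, "scale"), "normalized")
})

test_that("probe-set summarization averages on the log2 scale", {
  m <- matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
              dimnames = list(c("ps1", "ps2", "ps3"), c("s1", "s2")))
  em <- expression_matrix(m, platform = "exon_array",
                          scale = "log2_intensity")
  out <- summarize_probesets(em, list(iso = c("ps1", "ps2", "ps3")))
  expect_equal(unname(unclass(out)["iso", ]), c(4, 3))
  # averaging log2 values is NOT the log2 of the linear-scale mean
  expect_false(isTRUE(all.equal(4, log2((4 + 16 + 64) / 3))))
  expect_equal(log2((4 + 16 + 64) / 3), 4.80735, tolerance = 1e-5)
  # single-probe-set map is the identity (the probe-set-2858408-style case)
  one <- summarize_probesets(em, list(iso = "ps2"))
  expect_equal(unname(unclass(one)["iso", ]), unname(m["ps2", ]))
})

test_that("probe-set summary stays within the contributing probe sets", {
  set.seed(21)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    m <- matrix(rnorm(k * 4, 6, 2), k, 4,
                dimnames = list(paste0("ps", 1:k), paste0("s", 1:4)))
    em <- expression_matrix(m, platform = "exon_array",
                            scale = "log2_intensity")
    out <- unclass(summarize_probesets(em, list(iso = paste0("ps", 1:k))))
    expect_true(all(out["iso", ] >= apply(m, 2, min) - 1e-12))
    expect_true(all(out["iso", ] <= apply(m, 2, max) + 1e-12))
  }
})

test_that("probe-set summarization validates its map", {
  em <- expression_matrix(
    matrix(5.3, 1, 1, dimnames = list("ps1", "s1")),
    platform = "exon_array", scale = "log2_intensity")
  expect_error(summarize_probesets(em, list()),
               class = "fusionstrat_validation_error")
  expect_error(summarize_probesets(em, list(iso = character(0))),
               class = "fusionstrat_validation_error")
  expect_error(summarize_probesets(em, list(iso = "nope")),
               class = "fusionstrat_key_error")
})

test_that("TPM transform is log2(TPM + 1) and strictly increasing", {
  m <- matrix(c(0, 1, 1023, 7), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  em <- expression_matrix(m, platform = "rnaseq", scale = "tpm")
  out <- unclass(transform_tpm(em))
  expect_equal(unname(out[, 1])[1:3], c(0, 1, 10))
  tpm <- sort(runif(50, 0, 1e4))
  em2 <- expression_matrix(matrix(tpm, 1, dimnames =
                                    list("g", paste0("s", 1:50))),
                           platform = "rnaseq", scale = "tpm")
  expect_true(all(diff(unclass(transform_tpm(em2))[1, ]) > 0))
  bad <- expression_matrix(matrix(-1, 1, 1, dimnames = list("g", "s")),
                           platform = "rnaseq", scale = "tpm")
  expect_error(transform_tpm(bad), class = "fusionstrat_validation_error")
})

test_that("centering zeroes the mean and preserves differences exactly", {
  expect_equal(center_expression(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center_expression(c(5, 5, 5)), c(0, 0, 0))
  expect_error(center_expression(numeric(0)),
               class = "fusionstrat_validation_error")
  set.seed(31)
  x <- rnorm(40, 8, 3)
  cx <- center_expression(x)
  expect_lt(abs(mean(cx)), 1e-12)
  expect_identical(order(cx), order(x))
  expect_equal(outer(cx, cx, "-"), outer(x, x, "-"))
})

test_that("expression tables round-trip through disk", {
  set.seed(41)
  m <- matrix(round(rnorm(12, 8, 2), 6), 3, 4,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  em <- expression_matrix(m, platform = "exon_array",
                          scale = "log2_intensity")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path, platform = "exon_array",
                                 scale = "log2_intensity")
  expect_equal(unclass(back), unclass(em), tolerance = 1e-9)
})

test_that("samples with missing biomarker values are dropped, not imputed", {
  m <- matrix(c(1, 2, NA, 4, 5, 6), 2, 3,
              dimnames = list(c("PDE4D7", "ERG"), paste0("s", 1:3)))
  em <- expression_matrix(m, platform = "rnaseq", scale = "normalized",
                          allow_missing = TRUE)
  expect_warning(out <- drop_incomplete_samples(em, "PDE4D7"),
                 "dropping 1 sample")
  expect_identical(colnames(out), c("s1", "s3"))
})
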