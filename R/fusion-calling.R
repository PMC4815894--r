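#' Fusion-caller configuration
#'
#' Settings for expression-based TMPRSS2-ERG fusion calling. The default
#' method transforms log2 ERG expression to robust z-scores,
#' `z = (x - median) / MAD`, and calls samples with `z > threshold` positive.
#' The MAD here is the raw median absolute deviation, exactly as the robust
#' z-score is usually written in outlier work; the conventional 1.4826
#' normal-consistency factor can be switched on with `mad_consistency`, which
#' rescales z by 1/1.4826 and so makes the threshold slightly more stringent.
#'
#' @param method `"zscore"` (robust z-score outlier rule) or `"pam"`
#'   (two-medoid clustering fallback, see [call_fusion_pam()]).
#' @param threshold positive z-score cutoff; strictly greater-than (a sample
#'   at exactly the threshold is negative). Default 3.
#' @param mad_consistency apply the 1.4826 consistency factor to the MAD
#'   (default `FALSE`: raw MAD).
#' @param reference_pool which samples contribute to the median/MAD:
#'   `"all"` (default) or `"tumours_only"`.
#' @return a `fusion_caller_config` list.
#' @export
fusion_caller_config <- function(method = c("zscore", "pam"),
                                 threshold = 3,
                                 mad_consistency = FALSE,
                                 reference_pool = c("all", "tumours_only")) {
  method <- match.arg(method)
  reference_pool <- match.arg(reference_pool)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_validation("threshold must be a single positive number")
  }
  structure(list(method = method, threshold = threshold,
                 mad_consistency = isTRUE(mad_consistency),
                 reference_pool = reference_pool),
            class = "fusion_caller_config")
}

#' Robust z-scores against a reference pool
#'
#' `z_i = (x_i - median(pool)) / MAD(pool)`, with median and MAD computed over
#' the reference pool only and z returned for every sample. Because both the
#' location and the scale are robust order statistics, the z-scores are
#' invariant under adding a constant to all values or multiplying all values
#' by a positive constant.
#'
#' @param expr numeric vector of log2 expression values.
#' @param pool integer indices of the samples forming the reference pool
#'   (default: all samples). Must have length >= 3 and a positive MAD.
#' @param mad_consistency apply the 1.4826 consistency factor (default raw MAD).
#' @return numeric vector of z-scores, one per element of `expr`.
#' @export
#'
#' @examples
#' robust_zscores(c(1, 2, 3, 4, 100))  # -2 -1 0 1 97
robust_zscores <- function(expr, pool = seq_along(expr),
                           mad_consistency = FALSE) {
  assert_finite(expr, "expression values")
  if (!all(pool %in% seq_along(expr))) {
    stop_validation("pool indices out of range")
  }
  if (length(pool) < 3L) {
    fs_stop(sprintf("reference pool has %d samples; >= 3 required",
                    length(pool)),
            "fusionstrat_insufficient_data_error")
  }
  ref <- expr[pool]
  ctr <- stats::median(ref)
  scale_mad <- stats::mad(ref, center = ctr,
                          constant = if (isTRUE(mad_consistency)) 1.4826 else 1)
  if (scale_mad == 0) {
    stop_degenerate(sprintf(
      "MAD of the reference pool (%d samples) is zero; z-scores undefined",
      length(pool)))
  }
  (expr - ctr) / scale_mad
}

#' Call fusion status by the robust z-score outlier rule
#'
#' Samples whose ERG z-score strictly exceeds the configured threshold are
#' called fusion-positive. The rule works because the fusion places ERG under
#' an active promoter in a minority of samples: as long as positives are the
#' minority, the pooled median/MAD track the fusion-negative background and
#' positives appear as extreme outliers. When positives approach half the
#' pool the median migrates between the two expression modes and sensitivity
#' collapses — use [call_fusion_pam()] in that regime.
#'
#' @param expr numeric vector of log2 ERG expression values.
#' @param config a [fusion_caller_config()].
#' @param sample_ids sample identifiers (default `names(expr)` or indices).
#' @param pool reference-pool indices forwarded to [robust_zscores()].
#' @return a `data.frame` with columns `sample_id`, `method`, `z`, `call`
#'   (`"positive"`/`"negative"`).
#' @export
call_fusion_zscore <- function(expr, config = fusion_caller_config(),
                               sample_ids = NULL,
                               pool = seq_along(expr)) {
  sample_ids <- resolve_sample_ids(expr, sample_ids)
  z <- robust_zscores(expr, pool = pool,
                      mad_consistency = config$mad_consistency)
  data.frame(sample_id = sample_ids,
             method = "zscore",
             z = unname(z),
             call = ifelse(z > config$threshold, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Call fusion status by one-dimensional two-medoid clustering
#'
#' Partitions samples into two clusters of ERG expression and labels the
#' cluster with the higher medoid fusion-positive. In one dimension the
#' globally optimal 2-medoid partition (minimum total absolute deviation from
#' cluster medoids) is contiguous in sorted order, so it is found exactly by
#' exhaustive search over the n-1 contiguous split points — no random
#' initialization, hence a deterministic result for fixed input.
#'
#' @param log2_erg numeric vector of log2 ERG expression (>= 2 samples with
#'   >= 2 distinct values).
#' @param sample_ids sample identifiers (default `names` or indices).
#' @return a `data.frame` with columns `sample_id`, `method`, `z` (`NA` for
#'   this method), `call`.
#' @export
#'
#' @examples
#' call_fusion_pam(c(0.1, 0.2, 0.15, 8.0, 8.2, 7.9))$call
call_fusion_pam <- function(log2_erg, sample_ids = NULL) {
  sample_ids <- resolve_sample_ids(log2_erg, sample_ids)
  assert_finite(log2_erg, "log2 ERG expression")
  n <- length(log2_erg)
  if (n < 2L) stop_validation("two-medoid clustering needs >= 2 samples")
  if (length(unique(log2_erg)) < 2L) {
    stop_degenerate("all ERG values identical; two clusters undefined")
  }
  ord <- order(log2_erg)
  xs <- log2_erg[ord]
  # cost of a sorted block = sum |x - lower median|; the lower median is a
  # valid medoid and deterministic for even block sizes
  block_cost <- function(block) sum(abs(block - lower_median(block)))
  costs <- vapply(seq_len(n - 1L), function(k) {
    block_cost(xs[seq_len(k)]) + block_cost(xs[(k + 1L):n])
  }, numeric(1))
  k <- which.min(costs)  # ties -> smallest split, deterministic
  positive_sorted <- c(rep(FALSE, k), rep(TRUE, n - k))
  positive <- logical(n)
  positive[ord] <- positive_sorted
  data.frame(sample_id = sample_ids,
             method = "pam",
             z = NA_real_,
             call = ifelse(positive, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Call fusion status
#'
#' Dispatches to the z-score rule or the two-medoid fallback according to the
#' configuration.
#'
#' @inheritParams call_fusion_zscore
#' @return a fusion-call `data.frame` (see [call_fusion_zscore()]).
#' @export
call_fusion <- function(expr, config = fusion_caller_config(),
                        sample_ids = NULL, pool = seq_along(expr)) {
  switch(config$method,
         zscore = call_fusion_zscore(expr, config, sample_ids, pool),
         pam = call_fusion_pam(expr, sample_ids))
}

lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

resolve_sample_ids <- function(expr, sample_ids) {
  if (is.null(sample_ids)) sample_ids <- names(expr)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(expr))
  if (length(sample_ids) != length(expr)) {
    stop_validation("sample_ids must match the expression vector length")
  }
  sample_ids
}

#' Write fusion calls
#'
#' Tab-separated table: `sample_id`, `method`, `z` (or NA), `call`.
#'
#' @param calls a fusion-call `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fusion_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
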