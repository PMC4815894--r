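#' Normalize a qPCR Ct value against reference genes
#'
#' Delta-Ct normalization: the Ct value of the gene of interest is subtracted
#' from the arithmetic mean of the reference-gene Ct values,
#' \deqn{N = \mathrm{mean}(Ct_{ref}) - Ct_{goi},}
#' so that a higher normalized value means higher expression (Ct counts PCR
#' cycles: abundant transcripts cross threshold earlier, at lower Ct). The
#' result is invariant under any additive shift applied to all Cts of a
#' sample, which is what makes values comparable across runs.
#'
#' @param ct_goi numeric vector of Ct values for the gene of interest (one per
#'   sample).
#' @param ct_refs reference-gene Ct values: a numeric vector (one sample) or a
#'   matrix with reference genes in rows and samples in columns.
#' @return numeric vector of normalized expression values.
#' @export
#'
#' @examples
#' normalize_qpcr(25, c(24, 26))   # 0: gene sits at the reference mean
#' normalize_qpcr(22, c(24, 26))   # 3: ~8-fold above the reference mean
normalize_qpcr <- function(ct_goi, ct_refs) {
  if (length(ct_refs) == 0L) {
    fs_stop("at least one reference-gene Ct is required",
            "fusionstrat_missing_reference_error")
  }
  assert_finite(ct_goi, "Ct values (gene of interest)")
  assert_finite(ct_refs, "Ct values (reference genes)")
  ref_mean <- if (is.matrix(ct_refs)) colMeans(ct_refs) else mean(ct_refs)
  if (is.matrix(ct_refs) && ncol(ct_refs) != length(ct_goi)) {
    stop_validation("reference Ct matrix must have one column per sample")
  }
  unname(ref_mean - ct_goi)
}

#' Normalize a qPCR Ct matrix
#'
#' Applies [normalize_qpcr()] to every non-reference feature of a Ct-scale
#' expression matrix, using the named reference genes.
#'
#' @param x an [expression_matrix()] with `scale = "ct"`.
#' @param reference_genes character vector of feature ids used as references.
#' @return an `expression_matrix` on the `"normalized"` scale, reference rows
#'   dropped.
#' @export
normalize_qpcr_matrix <- function(x, reference_genes) {
  if (em_scale(x) != "ct") stop_validation("matrix scale must be 'ct'")
  if (length(reference_genes) == 0L) {
    fs_stop("no reference genes configured",
            "fusionstrat_missing_reference_error")
  }
  missing_refs <- setdiff(reference_genes, rownames(x))
  if (length(missing_refs)) {
    stop_config(sprintf("reference genes absent from matrix: %s",
                        paste(missing_refs, collapse = ", ")))
  }
  refs <- unclass(x)[reference_genes, , drop = FALSE]
  goi <- setdiff(rownames(x), reference_genes)
  if (length(goi) == 0L) stop_validation("no non-reference features to normalize")
  ref_mean <- colMeans(refs)
  values <- sweep(-unclass(x)[goi, , drop = FALSE], 2L, ref_mean, "+")
  em_retag(x, values, "normalized")
}

#' Summarize probe sets into isoform-level expression
#'
#' Exon-array isoform expression is the arithmetic mean of the log2
#' intensities of the isoform-specific probe sets (mean taken on the log2
#' scale, not the linear scale). A single-probe-set map returns that probe
#' set's values unchanged, covering datasets where only one probe set has
#' usable signal.
#'
#' @param x an [expression_matrix()] with `scale = "log2_intensity"`.
#' @param probeset_map named list: isoform name -> character vector of
#'   probe-set ids present in `x`.
#' @return an `expression_matrix` with one row per isoform, scale
#'   `"normalized"`.
#' @export
#'
#' @examples
#' m <- matrix(c(2, 4, 6), 3, 1,
#'             dimnames = list(c("ps1", "ps2", "ps3"), "s1"))
#' em <- expression_matrix(m, platform = "exon_array", scale = "log2_intensity")
#' summarize_probesets(em, list(iso = c("ps1", "ps2", "ps3")))  # 4.0
summarize_probesets <- function(x, probeset_map) {
  if (em_scale(x) != "log2_intensity") {
    stop_validation("matrix scale must be 'log2_intensity'")
  }
  if (!is.list(probeset_map) || length(probeset_map) == 0L ||
      is.null(names(probeset_map)) || any(!nzchar(names(probeset_map)))) {
    stop_validation("probeset_map must be a non-empty named list")
  }
  if (any(lengths(probeset_map) == 0L)) {
    stop_validation("every isoform must map to >= 1 probe set")
  }
  unmapped <- setdiff(unlist(probeset_map), rownames(x))
  if (length(unmapped)) {
    fs_stop(sprintf("probe sets absent from matrix: %s",
                    paste(unmapped, collapse = ", ")),
            "fusionstrat_key_error")
  }
  values <- t(vapply(probeset_map, function(ps) {
    colMeans(unclass(x)[ps, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(values) <- names(probeset_map)
  em_retag(x, values, "normalized")
}

#' Log-transform TPM expression
#'
#' `log2(TPM + pseudocount)`; with the default pseudocount of 1 a TPM of 0
#' maps to 0 and the transform is strictly increasing.
#'
#' @param x an [expression_matrix()] with `scale = "tpm"`, all values >= 0.
#' @param pseudocount positive offset added before the log (default 1).
#' @return an `expression_matrix` on the `"normalized"` scale.
#' @export
transform_tpm <- function(x, pseudocount = 1) {
  if (em_scale(x) != "tpm") stop_validation("matrix scale must be 'tpm'")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop_validation("pseudocount must be a single positive number")
  }
  if (any(unclass(x) < 0)) stop_validation("TPM values must be >= 0")
  em_retag(x, log2(unclass(x) + pseudocount), "normalized")
}

#' Mean-center expression values
#'
#' Subtracts the mean of the supplied values, so the output averages zero.
#' Centering is a monotone shift: ordering and all pairwise differences are
#' preserved exactly. Used for ranked-sample reporting where each sample is
#' shown relative to the sample-set mean.
#'
#' @param values numeric vector of normalized expression values.
#' @return centered numeric vector (names preserved).
#' @export
#'
#' @examples
#' center_expression(c(1, 2, 3))  # -1 0 1
center_expression <- function(values) {
  if (length(values) == 0L) stop_validation("cannot center an empty vector")
  assert_finite(values, "expression values")
  values - mean(values)
}

#' Drop samples with missing values in required features
#'
#' Samples missing any of the required features' measurements are removed with
#' a warning naming the count; no imputation is attempted.
#'
#' @param x an `expression_matrix` (may contain NA).
#' @param features feature ids that must be non-missing.
#' @return the matrix restricted to complete samples.
#' @export
drop_incomplete_samples <- function(x, features = rownames(x)) {
  absent <- setdiff(features, rownames(x))
  if (length(absent)) {
    fs_stop(sprintf("features absent from matrix: %s",
                    paste(absent, collapse = ", ")),
            "fusionstrat_key_error")
  }
  ok <- colSums(is.na(unclass(x)[features, , drop = FALSE])) == 0L
  if (!all(ok)) {
    warning(sprintf("dropping %d sample(s) with missing values in: %s",
                    sum(!ok), paste(features, collapse = ", ")))
  }
  structure(unclass(x)[, ok, drop = FALSE], platform = attr(x, "platform"),
            scale = attr(x, "scale"), class = class(x))
}
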