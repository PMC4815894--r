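#' Expression matrix container
#'
#' A features x samples numeric matrix tagged with its platform of origin and
#' measurement scale. Three platform dialects are supported: `qpcr` (raw Ct
#' values, scale `"ct"`), `exon_array` (RMA-style probe-set intensities, scale
#' `"log2_intensity"`) and `rnaseq` (transcripts per million, scale `"tpm"`).
#' After platform-specific normalization the scale becomes `"normalized"`, the
#' common log2-like scale on which all downstream analysis operates.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids character vectors; default to the dimnames of
#'   `values`.
#' @param platform one of `"qpcr"`, `"exon_array"`, `"rnaseq"`.
#' @param scale one of `"ct"`, `"log2_intensity"`, `"tpm"`, `"normalized"`.
#' @param allow_missing if `TRUE`, `NA` entries are tolerated (they must be
#'   resolved with [drop_incomplete_samples()] before analysis); non-finite
#'   values other than `NA` are always rejected.
#'
#' @return An object of class `expression_matrix`: the matrix with `platform`
#'   and `scale` attributes.
#' @export
#'
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("ERG", "PDE4D7"), paste0("s", 1:3)))
#' expression_matrix(m, platform = "rnaseq", scale = "tpm")
expression_matrix <- function(values,
                              feature_ids = rownames(values),
                              sample_ids = colnames(values),
                              platform = c("qpcr", "exon_array", "rnaseq"),
                              scale = c("ct", "log2_intensity", "tpm",
                                        "normalized"),
                              allow_missing = FALSE) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("'values' must be a numeric matrix")
  }
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop_validation("feature and sample ids are required (set dimnames)")
  }
  if (length(feature_ids) != nrow(values) ||
      length(sample_ids) != ncol(values)) {
    stop_validation("id lengths must match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) stop_validation("sample ids must be unique")
  if (anyDuplicated(feature_ids)) stop_validation("feature ids must be unique")
  if (allow_missing) {
    if (any(!is.finite(values) & !is.na(values))) {
      stop_validation("expression values must be finite or NA")
    }
  } else {
    assert_finite(values, "expression values")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, platform = platform, scale = scale,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples [%s, scale=%s]\n",
              nrow(x), ncol(x), attr(x, "platform"), attr(x, "scale")))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE]))
  invisible(x)
}

em_platform <- function(x) attr(x, "platform")
em_scale <- function(x) attr(x, "scale")

# Retag after a transform, preserving class and dimnames.
em_retag <- function(x, values, scale) {
  structure(values, platform = attr(x, "platform"), scale = scale,
            class = class(x))
}

#' Read / write expression tables
#'
#' Tab-separated text, features in rows, samples in columns, first column the
#' feature id, header row of sample ids — the on-disk dialect shared by all
#' three platforms.
#'
#' @param path file path.
#' @param platform,scale platform/scale tags for the matrix read (see
#'   [expression_matrix()]).
#' @param allow_missing tolerate `NA` cells when reading (default `TRUE`;
#'   resolve them with [drop_incomplete_samples()]).
#' @return `read_expression_matrix` returns an `expression_matrix`;
#'   `write_expression_matrix` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, platform, scale,
                                   allow_missing = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_validation("expression table needs >= 2 columns")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1L]])
  expression_matrix(values, platform = platform, scale = scale,
                    allow_missing = allow_missing)
}

#' @rdname read_expression_matrix
#' @param x an `expression_matrix`.
#' @export
write_expression_matrix <- function(x, path) {
  tab <- data.frame(feature_id = rownames(x), unclass(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
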