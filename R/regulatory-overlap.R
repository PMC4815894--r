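#' Genomic intervals (BED-style, 0-based half-open)
#'
#' All overlap arithmetic in this package uses the BED convention: intervals
#' are `[start, end)` on 0-based coordinates, so two intervals that merely
#' touch (one's end equals the other's start) do not overlap. GFF-style
#' 1-based inputs must be converted at the reading boundary.
#'
#' @param chrom chromosome names (non-empty strings).
#' @param start,end non-negative integer coordinates with `start < end`.
#' @param name optional interval names.
#' @param strand optional strand (`"+"`, `"-"`, `"."`); ignored by overlap
#'   operations (ChIP-seq peaks are unstranded).
#' @return a `data.frame` of class `genomic_intervals`.
#' @export
#'
#' @examples
#' genomic_intervals("chr5", 1000, 2000, name = "region")
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = ".") {
  n <- length(chrom)
  if (n == 0L) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      strand = character(), stringsAsFactors = FALSE)
    class(out) <- c("genomic_intervals", "data.frame")
    return(out)
  }
  if (!is.character(chrom) || any(!nzchar(chrom)) || anyNA(chrom)) {
    stop_validation("chrom must be non-empty strings")
  }
  assert_finite(start, "start")
  assert_finite(end, "end")
  if (any(start < 0)) stop_validation("start must be >= 0")
  if (any(start >= end)) stop_validation("intervals require start < end")
  if (!all(strand %in% c("+", "-", ".") | is.na(strand))) {
    stop_validation("strand must be one of '+', '-', '.'")
  }
  out <- data.frame(chrom = chrom, start = as.numeric(start),
                    end = as.numeric(end),
                    name = rep_len(as.character(name), n),
                    strand = rep_len(as.character(strand), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

as_genomic_intervals <- function(x) {
  if (inherits(x, "genomic_intervals")) return(x)
  if (is.data.frame(x) && all(c("chrom", "start", "end") %in% names(x))) {
    return(genomic_intervals(x$chrom, x$start, x$end,
                             if ("name" %in% names(x)) x$name else NA,
                             if ("strand" %in% names(x)) x$strand else "."))
  }
  stop_validation("expected genomic intervals (chrom, start, end)")
}

# 0-based half-open -> GRanges (1-based closed); a shared seqlevel universe
# avoids spurious cross-object seqinfo warnings
as_granges <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Extend a region by flanking sequence
#'
#' Adds `size` bases on each side, clipping the start at 0 (no chromosome-end
#' clipping: lengths are not assumed known). The common use is widening a
#' gene region by 50 kb before intersecting with ChIP-seq peaks, so binding
#' events in nearby regulatory sequence are counted as well.
#'
#' @param region a single-row [genomic_intervals()] object.
#' @param size flank size in bases, >= 0.
#' @return the flanked region.
#' @export
#'
#' @examples
#' flank_region(genomic_intervals("chr5", 1000, 2000), 500)
flank_region <- function(region, size) {
  region <- as_genomic_intervals(region)
  if (nrow(region) != 1L) stop_validation("region must be a single interval")
  if (!is.numeric(size) || length(size) != 1L || !is.finite(size) ||
      size < 0) {
    stop_validation("flank size must be a single number >= 0")
  }
  genomic_intervals(region$chrom, max(0, region$start - size),
                    region$end + size, region$name, region$strand)
}

#' Count peaks overlapping a region
#'
#' Overlap under half-open semantics on the same chromosome:
#' `peak.start < region.end && region.start < peak.end`. Strand is ignored.
#' For peaks that do not overlap, the gap to the region (in bases, 0 for
#' touching intervals) is reported so near-miss peaks — e.g. within 200
#' bases of a promoter — can be flagged.
#'
#' @param peaks a [genomic_intervals()] object (e.g. ChIP-seq peaks).
#' @param region a single-row [genomic_intervals()] object.
#' @param proximity_limit distance (bases) below which a non-overlapping peak
#'   is flagged as proximal (default 200).
#' @return a list: `count`, `overlapping` (the overlapping subset),
#'   `distances` (per input peak: 0 if overlapping, else gap in bases, `NA`
#'   on other chromosomes), `proximal` (non-overlapping peaks with distance
#'   < `proximity_limit`).
#' @export
count_overlaps_region <- function(peaks, region, proximity_limit = 200) {
  peaks <- as_genomic_intervals(peaks)
  region <- as_genomic_intervals(region)
  if (nrow(region) != 1L) stop_validation("region must be a single interval")
  if (nrow(peaks) == 0L) {
    return(list(count = 0L, overlapping = peaks,
                distances = numeric(0), proximal = peaks))
  }
  same <- peaks$chrom == region$chrom
  lvls <- unique(c(peaks$chrom, region$chrom))
  gr_peaks <- as_granges(peaks, lvls)
  gr_region <- as_granges(region, lvls)
  hits <- GenomicRanges::countOverlaps(gr_peaks, gr_region,
                                       ignore.strand = TRUE) > 0
  # distance() counts bases strictly between ranges; adjacent -> 0
  dist <- rep(NA_real_, nrow(peaks))
  if (any(same)) {
    dist[same] <- GenomicRanges::distance(gr_peaks[same], gr_region,
                                          ignore.strand = TRUE)
  }
  dist[hits] <- 0
  proximal_idx <- which(!hits & same & dist < proximity_limit)
  list(count = sum(hits),
       overlapping = peaks[hits, , drop = FALSE],
       distances = dist,
       proximal = peaks[proximal_idx, , drop = FALSE])
}

#' Read / write BED files
#'
#' Standard BED (3+ columns) via `rtracklayer`, returned as 0-based
#' half-open [genomic_intervals()].
#'
#' @param path file path.
#' @return `read_bed` returns a `genomic_intervals` object; `write_bed`
#'   returns `path` invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = nm,
    strand = as.character(GenomicRanges::strand(gr)) |>
      (\(s) ifelse(s == "*", ".", s))())
}

#' @rdname read_bed
#' @param x a `genomic_intervals` object.
#' @export
write_bed <- function(x, path) {
  x <- as_genomic_intervals(x)
  tab <- data.frame(chrom = x$chrom,
                    start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    name = ifelse(is.na(x$name), ".", x$name),
                    score = 0L,
                    strand = ifelse(is.na(x$strand), ".", x$strand))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a `chrom:start-end` region string
#'
#' Convenience for command-line use; coordinates are taken as 0-based
#' half-open, matching BED.
#'
#' @param spec a string like `"chr5:58264866-59817947"`.
#' @return a single-row [genomic_intervals()] object.
#' @export
parse_region <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1L]]
  if (length(m) != 4L) {
    stop_validation("region must look like 'chrom:start-end'")
  }
  genomic_intervals(m[2L], as.numeric(m[3L]), as.numeric(m[4L]))
}
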