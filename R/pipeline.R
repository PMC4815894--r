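#' Analysis configuration
#'
#' Collects the knobs of the end-to-end analysis: which features carry the
#' biomarker and ERG expression, the fusion-caller settings, the Gleason
#' grouping (groups 1-4 = 3+3, 3+4, 4+3, >=4+4; low grade = groups 1-2
#' i.e. <=3+4, high grade = groups 3-4 i.e. >=4+3), the recurrence-dichotomy
#' and follow-up horizons (24 and 60 months), the survival endpoint and the
#' expression-cutoff mode.
#'
#' @param goi biomarker feature id (default `"PDE4D7"`).
#' @param erg_feature ERG feature id used for fusion calling.
#' @param fusion a [fusion_caller_config()].
#' @param gleason_low,gleason_high integer Gleason group indices forming the
#'   low/high grade strata.
#' @param dichotomy_horizon months splitting early vs late recurrence
#'   (default 24).
#' @param followup_horizon months of the with/without-event comparison
#'   window (default 60).
#' @param endpoint `"BCR"` or `"CR"`.
#' @param cutoff `"auto"` (derive from the ROC of expression against early
#'   vs late recurrence, at maximum sensitivity + specificity) or a fixed
#'   numeric cutoff.
#' @param seed integer seed recorded in the run manifest.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(goi = "PDE4D7",
                            erg_feature = "ERG",
                            fusion = fusion_caller_config(),
                            gleason_low = c(1L, 2L),
                            gleason_high = c(3L, 4L),
                            dichotomy_horizon = 24,
                            followup_horizon = 60,
                            endpoint = c("BCR", "CR"),
                            cutoff = "auto",
                            seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (!identical(cutoff, "auto") &&
      !(is.numeric(cutoff) && length(cutoff) == 1L && is.finite(cutoff))) {
    stop_config("cutoff must be 'auto' or a single finite number")
  }
  if (length(intersect(gleason_low, gleason_high))) {
    stop_config("gleason_low and gleason_high must be disjoint")
  }
  structure(list(goi = goi, erg_feature = erg_feature, fusion = fusion,
                 gleason_low = as.integer(gleason_low),
                 gleason_high = as.integer(gleason_high),
                 dichotomy_horizon = dichotomy_horizon,
                 followup_horizon = followup_horizon,
                 endpoint = endpoint, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

comparison_row <- function(contrast, label_a, label_b, a, b) {
  mw <- mann_whitney(a, b, label_a, label_b)
  auc <- roc_auc(c(a, b), c(rep(1L, length(a)), rep(0L, length(b))))
  data.frame(contrast = contrast,
             group_a = label_a, group_b = label_b,
             n_a = mw$n_a, n_b = mw$n_b,
             median_a = mw$median_a, median_b = mw$median_b,
             U = mw$U, p_value = mw$p_value,
             auc = auc$auc, auc_ci_low = auc$ci_low,
             auc_ci_high = auc$ci_high,
             stringsAsFactors = FALSE)
}

# a contrast is skipped (with a log line) rather than fatal when a stratum
# is too small; real cohorts do not guarantee every stratum is occupied
safe_comparison <- function(contrast, label_a, label_b, a, b, min_n = 2L) {
  if (length(a) < min_n || length(b) < min_n) {
    message(sprintf("skipping contrast '%s' (%d vs %d samples)",
                    contrast, length(a), length(b)))
    return(NULL)
  }
  comparison_row(contrast, label_a, label_b, a, b)
}

#' Run the full expression-stratification analysis
#'
#' Orchestrates, on one normalized dataset: ERG-based fusion calling; the
#' tissue-class and fusion-stratified biomarker contrasts; the Gleason
#' low-vs-high grade contrast within each fusion stratum; the with- vs
#' without-recurrence contrast inside the follow-up window; the ROC-derived
#' expression cutoff and the cutoff-stratified survival comparison; and the
#' ranked-sample report. Samples from the `NAT` tissue class never enter
#' Gleason or survival analyses.
#'
#' @param expression an [expression_matrix()] on the `"normalized"` scale
#'   containing the biomarker and ERG features.
#' @param annotation data frame with columns `sample_id`, `tissue`,
#'   `gleason_group`, `time_months`, `event` (and optionally `endpoint`).
#' @param config an [analysis_config()].
#' @return an `analysis_report` list: `fusion_calls`, `comparisons` (one row
#'   per contrast), `cutoff` (a `cutoff_result` or the fixed value),
#'   `survival` (a [hazard_ratio()] comparison from
#'   [stratify_by_cutoff()], or `NULL` if not estimable), `ranked`
#'   (a [rank_samples()] report), `manifest`.
#' @export
run_pipeline <- function(expression, annotation, config = analysis_config()) {
  if (em_scale(expression) != "normalized") {
    stop_validation("expression must be on the 'normalized' scale")
  }
  need <- c(config$goi, config$erg_feature)
  if (!all(need %in% rownames(expression))) {
    fs_stop(sprintf("features missing from matrix: %s",
                    paste(setdiff(need, rownames(expression)),
                          collapse = ", ")),
            "fusionstrat_key_error")
  }
  if (!all(c("sample_id", "tissue") %in% names(annotation))) {
    stop_validation("annotation needs sample_id and tissue columns")
  }
  ids <- intersect(colnames(expression), annotation$sample_id)
  if (length(ids) == 0L) {
    stop_validation("no samples shared between expression and annotation")
  }
  ann <- annotation[match(ids, annotation$sample_id), , drop = FALSE]
  goi <- stats::setNames(unclass(expression)[config$goi, ids], ids)
  erg <- stats::setNames(unclass(expression)[config$erg_feature, ids], ids)

  is_tumour <- ann$tissue != "NAT"
  pool <- if (config$fusion$reference_pool == "tumours_only") {
    which(is_tumour)
  } else {
    seq_along(erg)
  }
  calls <- call_fusion(erg, config$fusion, sample_ids = ids, pool = pool)
  fus_pos <- calls$call == "positive"

  comparisons <- list()
  # tissue-class and fusion-stratified contrasts
  comparisons$nat_vs_tumour <- safe_comparison(
    "tissue", "NAT", "tumour", goi[!is_tumour], goi[is_tumour])
  comparisons$nat_vs_fusion_neg <- safe_comparison(
    "fusion_strata", "NAT", "tumour_fusion_neg",
    goi[!is_tumour], goi[is_tumour & !fus_pos])
  comparisons$nat_vs_fusion_pos <- safe_comparison(
    "fusion_strata", "NAT", "tumour_fusion_pos",
    goi[!is_tumour], goi[is_tumour & fus_pos])
  comparisons$fusion_neg_vs_pos <- safe_comparison(
    "fusion_strata", "tumour_fusion_neg", "tumour_fusion_pos",
    goi[is_tumour & !fus_pos], goi[is_tumour & fus_pos])

  # Gleason low vs high grade, within each fusion stratum
  gl <- ann$gleason_group
  low <- !is.na(gl) & gl %in% config$gleason_low
  high <- !is.na(gl) & gl %in% config$gleason_high
  comparisons$gleason_fusion_pos <- safe_comparison(
    "gleason", "low_grade_fusion_pos", "high_grade_fusion_pos",
    goi[low & fus_pos], goi[high & fus_pos])
  comparisons$gleason_fusion_neg <- safe_comparison(
    "gleason", "low_grade_fusion_neg", "high_grade_fusion_neg",
    goi[low & fus_pos == FALSE & is_tumour],
    goi[high & fus_pos == FALSE & is_tumour])

  has_outcome <- all(c("time_months", "event") %in% names(annotation))
  cutoff_res <- NULL
  surv_comp <- NULL
  recurrence <- NULL
  if (has_outcome) {
    rec <- survival_records(ann$sample_id[is_tumour],
                            ann$time_months[is_tumour],
                            ann$event[is_tumour],
                            config$endpoint)
    # with vs without the event inside the follow-up window
    fu <- tryCatch(filter_followup(rec, config$followup_horizon),
                   error = function(e) NULL)
    if (!is.null(fu) && nrow(fu)) {
      g_ev <- goi[fu$sample_id[fu$followup_group == "event"]]
      g_no <- goi[fu$sample_id[fu$followup_group == "no_event"]]
      comparisons$followup <- safe_comparison(
        "followup_window", "no_event", "event", g_no, g_ev)
    }
    recurrence <- dichotomize_recurrence(rec, config$dichotomy_horizon)
    # cutoff from the ROC of expression against early vs late recurrence
    # among samples that experienced the event
    if (identical(config$cutoff, "auto")) {
      ev <- recurrence[recurrence != "no_event"]
      if (length(unique(ev)) == 2L && length(ev) >= 4L) {
        curve <- roc_curve(goi[names(ev)], ev == "late", direction = ">")
        cutoff_res <- optimal_cutoff(curve)
      } else {
        message("cutoff='auto' needs early and late recurrences; ",
                "skipping survival stratification")
      }
    } else {
      cutoff_res <- structure(list(cutoff = config$cutoff,
                                   sensitivity = NA_real_,
                                   specificity = NA_real_, J = NA_real_,
                                   direction = ">"),
                              class = "cutoff_result")
    }
    if (!is.null(cutoff_res)) {
      surv_comp <- tryCatch(
        stratify_by_cutoff(goi[rec$sample_id], cutoff_res$cutoff, rec),
        fusionstrat_error = function(e) {
          message("survival stratification skipped: ",
                  conditionMessage(e))
          NULL
        })
    }
  }

  ranked <- rank_samples(goi, ann, fusion_calls = calls,
                         recurrence = recurrence)

  report <- list(
    fusion_calls = calls,
    comparisons = do.call(rbind, Filter(Negate(is.null), comparisons)),
    cutoff = cutoff_res,
    survival = surv_comp,
    ranked = ranked,
    manifest = list(config = unclass(config),
                    seed = config$seed,
                    n_samples = length(ids),
                    n_tumour = sum(is_tumour),
                    n_fusion_positive = sum(fus_pos),
                    package_version =
                      as.character(utils::packageVersion("fusionstrat"))))
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d samples, %d fusion-positive\n",
              x$manifest$n_samples, x$manifest$n_fusion_positive))
  if (!is.null(x$comparisons)) {
    cat(sprintf("  %d group contrasts computed\n", nrow(x$comparisons)))
  }
  if (!is.null(x$cutoff)) {
    cat(sprintf("  expression cutoff: %.4g\n", x$cutoff$cutoff))
  }
  if (!is.null(x$survival)) print(x$survival$comparison)
  invisible(x)
}

#' Ranked-sample report
#'
#' Centers the normalized expression on the sample-set mean, ranks samples
#' by descending centered expression (ties broken by sample id for
#' determinism) and attaches the tissue class, called fusion status (or an
#' annotated status such as an ETV1/ETV4 rearrangement, passed through when
#' present in the annotation as a `fusion_status` column), Gleason group and
#' recurrence dichotomy.
#'
#' @param values named numeric vector of normalized expression.
#' @param annotation data frame with `sample_id`, `tissue` and optionally
#'   `gleason_group`, `fusion_status`.
#' @param fusion_calls optional fusion-call data frame (see
#'   [call_fusion()]); ignored for samples with an annotated status.
#' @param recurrence optional factor from [dichotomize_recurrence()].
#' @return a data frame sorted by rank: `rank`, `sample_id`,
#'   `centered_expression`, `tissue`, `fusion_status`, `gleason_group`,
#'   `recurrence`.
#' @export
rank_samples <- function(values, annotation, fusion_calls = NULL,
                         recurrence = NULL) {
  if (length(values) == 0L) stop_validation("no expression values to rank")
  if (is.null(names(values))) {
    stop_validation("values must be named by sample id")
  }
  centered <- center_expression(values)
  ids <- names(centered)
  ann <- annotation[match(ids, annotation$sample_id), , drop = FALSE]
  status <- rep(NA_character_, length(ids))
  if (!is.null(fusion_calls)) {
    m <- match(ids, fusion_calls$sample_id)
    status <- ifelse(is.na(m), status,
                     paste0("TMPRSS2-ERG_", fusion_calls$call[m]))
  }
  if ("fusion_status" %in% names(ann)) {
    annotated <- !is.na(ann$fusion_status) & nzchar(ann$fusion_status)
    status[annotated] <- ann$fusion_status[annotated]
  }
  rec <- if (!is.null(recurrence)) {
    as.character(recurrence[ids])
  } else {
    NA_character_
  }
  ord <- order(-centered, ids)
  out <- data.frame(rank = seq_along(ids),
                    sample_id = ids[ord],
                    centered_expression = unname(centered[ord]),
                    tissue = ann$tissue[ord],
                    fusion_status = status[ord],
                    gleason_group = if ("gleason_group" %in% names(ann)) {
                      ann$gleason_group[ord]
                    } else {
                      NA_integer_
                    },
                    recurrence = if (length(rec) > 1L) rec[ord] else rec,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an analysis report bundle
#'
#' Writes each table of a [run_pipeline()] report as tab-separated text plus
#' a YAML manifest carrying the configuration, seed and an md5 checksum of
#' every written file, so a bundle can be verified and reproduced from the
#' manifest alone. Identical inputs and configuration produce byte-identical
#' bundles.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  if (!inherits(report, "analysis_report")) {
    stop_validation("expected an analysis_report")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tab <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(write_tab(report$fusion_calls, "fusion_calls.tsv"),
             write_tab(report$ranked, "ranked_samples.tsv"))
  if (!is.null(report$comparisons)) {
    paths <- c(paths, write_tab(report$comparisons, "comparisons.tsv"))
  }
  if (!is.null(report$survival)) {
    cmp <- report$survival$comparison
    surv_tab <- data.frame(
      group = cmp$groups,
      n = vapply(cmp$curves, `[[`, numeric(1), "n"),
      events = unname(cmp$observed),
      expected = unname(cmp$expected),
      median_months = unname(cmp$medians),
      hr_high_vs_low = c(NA, cmp$hr),
      ci_low = c(NA, cmp$ci_low), ci_high = c(NA, cmp$ci_high),
      logrank_p = c(NA, cmp$p_value))
    paths <- c(paths, write_tab(surv_tab, "survival.tsv"))
    km_tab <- do.call(rbind, lapply(names(cmp$curves), function(g) {
      cv <- cmp$curves[[g]]
      if (length(cv$time) == 0L) return(NULL)
      data.frame(group = g, time_months = cv$time, surv = cv$surv,
                 n_risk = cv$n_risk, n_event = cv$n_event)
    }))
    if (!is.null(km_tab)) paths <- c(paths, write_tab(km_tab, "km_steps.tsv"))
  }
  manifest <- report$manifest
  if (!is.null(report$cutoff)) manifest$cutoff <- report$cutoff$cutoff
  manifest$files <- lapply(stats::setNames(paths, basename(paths)),
                           function(p) unname(tools::md5sum(p)))
  manifest$config$fusion <- unclass(manifest$config$fusion)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
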