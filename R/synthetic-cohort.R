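#' Synthetic cohort parameters
#'
#' Defines the statistical structure of a simulated prostate-cancer cohort:
#' a tissue mix of normal-adjacent (NAT) and tumour samples; bimodal log2 ERG
#' expression with a planted fraction of fusion-positive tumours; PDE4D7
#' expression built from a per-tissue baseline, an additive log2 shift in
#' fusion-positive tumours (default +1, i.e. 2-fold), and a per-Gleason-group
#' decline applied only to fusion-positive samples; and exponential
#' time-to-recurrence whose log-hazard is linear in normalized PDE4D7, with
#' uniform plus administrative censoring.
#'
#' The defaults place the generator in the regime the outlier-based fusion
#' caller assumes: fusion prevalence 0.4 (outlier calling degrades as the
#' positive fraction approaches 0.5, when the pooled median/MAD migrate
#' between the two ERG modes), ERG modes separated by 6 log2 units against a
#' background sd of 0.5, a 2-fold fusion effect on PDE4D7, and a 60-month
#' administrative follow-up horizon.
#'
#' @param n_samples number of samples (>= 2).
#' @param tissue_mix named proportions over tissue classes, summing to 1.
#' @param fusion_prevalence fraction of tumour samples that are
#'   fusion-positive, in `[0, 1)`.
#' @param erg_neg_mean,erg_neg_sd,erg_pos_mean,erg_pos_sd log2 ERG component
#'   parameters for fusion-negative / fusion-positive samples (sds > 0).
#' @param pde4d7_base named per-tissue-class mean of normalized PDE4D7 (log2
#'   units); must name every class in `tissue_mix`.
#' @param fusion_effect additive log2 shift of PDE4D7 in fusion-positive
#'   tumours (default 1.0 = 2-fold).
#' @param grade_effect additive log2 shift per Gleason-group step (centered
#'   at the mean group index), applied only to fusion-positive samples
#'   (negative = decline with grade).
#' @param noise_sd residual sd of PDE4D7 (log2 units, > 0 unless exactly 0
#'   for noise-free checks).
#' @param baseline_hazard recurrence hazard (events/month) at PDE4D7 = 0.
#' @param log_hr_per_unit change in log-hazard per unit of normalized PDE4D7
#'   (negative = high expression protective).
#' @param censor_uniform_max upper bound (months) of the uniform censoring
#'   time.
#' @param admin_horizon administrative censoring horizon in months
#'   (default 60, a 5-year follow-up window).
#' @param seed integer RNG seed; identical parameters and seed give
#'   byte-identical cohorts.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_samples = 500,
                          tissue_mix = c(NAT = 0.2, tumour = 0.8),
                          fusion_prevalence = 0.4,
                          erg_neg_mean = 0, erg_neg_sd = 0.5,
                          erg_pos_mean = 6, erg_pos_sd = 1,
                          pde4d7_base = c(NAT = 2, tumour = 2),
                          fusion_effect = 1.0,
                          grade_effect = -0.5,
                          noise_sd = 0.5,
                          baseline_hazard = 0.08,
                          log_hr_per_unit = -0.5,
                          censor_uniform_max = 120,
                          admin_horizon = 60,
                          seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2) {
    fs_stop("n_samples must be >= 2", "fusionstrat_invalid_parameter_error")
  }
  if (is.null(names(tissue_mix)) || any(!nzchar(names(tissue_mix)))) {
    stop_config("tissue_mix must be a named proportion vector")
  }
  if (abs(sum(tissue_mix) - 1) > 1e-9) {
    fs_stop("tissue_mix proportions must sum to 1",
            "fusionstrat_invalid_parameter_error")
  }
  if (any(tissue_mix < 0)) {
    fs_stop("tissue_mix proportions must be >= 0",
            "fusionstrat_invalid_parameter_error")
  }
  if (fusion_prevalence < 0 || fusion_prevalence >= 1) {
    fs_stop("fusion_prevalence must be in [0, 1)",
            "fusionstrat_invalid_parameter_error")
  }
  for (s in c(erg_neg_sd, erg_pos_sd)) {
    if (s <= 0) fs_stop("ERG component sds must be > 0",
                        "fusionstrat_invalid_parameter_error")
  }
  if (noise_sd < 0) {
    fs_stop("noise_sd must be >= 0", "fusionstrat_invalid_parameter_error")
  }
  missing_base <- setdiff(names(tissue_mix), names(pde4d7_base))
  if (length(missing_base)) {
    stop_config(sprintf("pde4d7_base missing tissue class(es): %s",
                        paste(missing_base, collapse = ", ")))
  }
  if (baseline_hazard <= 0) {
    fs_stop("baseline_hazard must be > 0",
            "fusionstrat_invalid_parameter_error")
  }
  structure(list(n_samples = as.integer(n_samples), tissue_mix = tissue_mix,
                 fusion_prevalence = fusion_prevalence,
                 erg_neg_mean = erg_neg_mean, erg_neg_sd = erg_neg_sd,
                 erg_pos_mean = erg_pos_mean, erg_pos_sd = erg_pos_sd,
                 pde4d7_base = pde4d7_base, fusion_effect = fusion_effect,
                 grade_effect = grade_effect, noise_sd = noise_sd,
                 baseline_hazard = baseline_hazard,
                 log_hr_per_unit = log_hr_per_unit,
                 censor_uniform_max = censor_uniform_max,
                 admin_horizon = admin_horizon, seed = as.integer(seed)),
            class = "cohort_params")
}

# deterministic class counts: floor(n * p), remainder to the largest
# fractional parts (ties by class order)
allocate_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under [cohort_params()]: tissue classes in fixed
#' deterministic proportions; for tumours, Gleason groups 1-4 (3+3, 3+4,
#' 4+3, >=4+4) uniform and a fixed fraction of fusion-positive samples;
#' log2 ERG from the fusion-negative or fusion-positive Gaussian component;
#' PDE4D7 as
#' `base(class) + fusion_effect*[fusion+] + grade_effect*(group-2.5)*[fusion+]
#' + N(0, noise_sd)` (the grade term is centered at the mean group index so
#' `fusion_effect` is the elevation of the typical-grade fusion-positive
#' tumour); and recurrence times from an exponential with hazard
#' `baseline_hazard * exp(log_hr_per_unit * PDE4D7)`, censored at the
#' earlier of a uniform censoring time and the administrative horizon.
#'
#' @param params a [cohort_params()] object.
#' @return a list of class `synthetic_cohort`:
#'   * `expression`: [expression_matrix()] with rows `ERG` and `PDE4D7`
#'     (scale `"normalized"`),
#'   * `annotation`: data frame with `sample_id`, `tissue`, `gleason_group`,
#'     `time_months`, `event`, `endpoint`,
#'   * `truth`: data frame with `sample_id`, `fusion`, `true_hazard`,
#'   * `params`: the parameters used.
#' @export
#'
#' @examples
#' cohort <- generate_cohort(cohort_params(n_samples = 50, seed = 7))
#' table(cohort$truth$fusion, cohort$annotation$tissue)
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    params <- do.call(cohort_params, params)
  }
  set.seed(params$seed)
  n <- params$n_samples
  classes <- names(params$tissue_mix)
  counts <- allocate_counts(n, params$tissue_mix)
  tissue <- rep(classes, counts)
  sample_id <- sprintf("S%04d", seq_len(n))

  is_tumour <- tissue != "NAT"
  gleason <- rep(NA_integer_, n)
  gleason[is_tumour] <- sample.int(4L, sum(is_tumour), replace = TRUE)

  fusion <- rep(FALSE, n)
  tum_idx <- which(is_tumour)
  n_pos <- round(params$fusion_prevalence * length(tum_idx))
  if (n_pos > 0) {
    fusion[sample(tum_idx, n_pos)] <- TRUE
  }

  erg <- ifelse(fusion,
                stats::rnorm(n, params$erg_pos_mean, params$erg_pos_sd),
                stats::rnorm(n, params$erg_neg_mean, params$erg_neg_sd))

  # grade term centered at the mean group index (2.5 under uniform 1-4), so
  # fusion_effect is the elevation of the typical-grade fusion+ tumour and
  # the planted ~2-fold fusion elevation survives a nonzero grade effect
  grade_step <- ifelse(is.na(gleason), 0, gleason - 2.5)
  pde4d7 <- params$pde4d7_base[tissue] +
    params$fusion_effect * fusion +
    params$grade_effect * grade_step * fusion +
    stats::rnorm(n, 0, params$noise_sd)
  pde4d7 <- unname(pde4d7)

  hazard <- params$baseline_hazard * exp(params$log_hr_per_unit * pde4d7)
  event_time <- stats::rexp(n, rate = hazard)
  censor_time <- pmin(stats::runif(n, 0, params$censor_uniform_max),
                      params$admin_horizon)
  time_months <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)

  values <- rbind(ERG = erg, PDE4D7 = pde4d7)
  colnames(values) <- sample_id
  expr <- expression_matrix(values, platform = "rnaseq",
                            scale = "normalized")
  annotation <- data.frame(sample_id = sample_id, tissue = tissue,
                           gleason_group = gleason,
                           time_months = time_months, event = event,
                           endpoint = "BCR", stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_id, fusion = fusion,
                      true_hazard = hazard, stringsAsFactors = FALSE)
  structure(list(expression = expr, annotation = annotation, truth = truth,
                 params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%s); %d fusion-positive; %d events\n",
    nrow(x$annotation),
    paste(sprintf("%s=%d", names(table(x$annotation$tissue)),
                  table(x$annotation$tissue)), collapse = ", "),
    sum(x$truth$fusion), sum(x$annotation$event)))
  invisible(x)
}

#' Generate a synthetic qPCR Ct plate
#'
#' Emits a Ct-scale expression matrix whose normalization round-trips to a
#' planted expression vector: the gene-of-interest Ct is
#' `intercept - expression + noise` (each doubling of expression lowers Ct
#' by one cycle) and each reference-gene Ct is drawn around the stable
#' `intercept`. With zero noise, [normalize_qpcr_matrix()] recovers the
#' planted values exactly; the output is also invariant under any constant
#' added to all Cts of a sample.
#'
#' @param expression named numeric vector of planted normalized expression
#'   (names = sample ids).
#' @param goi gene-of-interest feature name (default `"PDE4D7"`).
#' @param reference_genes names of reference genes (>= 1).
#' @param intercept Ct of a transcript at normalized expression 0
#'   (default 25 cycles).
#' @param noise_sd Ct measurement noise (cycles, default 0.1).
#' @param seed integer RNG seed.
#' @return an [expression_matrix()] with platform `"qpcr"`, scale `"ct"`.
#' @export
generate_qpcr_plate <- function(expression,
                                goi = "PDE4D7",
                                reference_genes = c("REF1", "REF2", "REF3"),
                                intercept = 25,
                                noise_sd = 0.1,
                                seed = 1L) {
  if (length(reference_genes) == 0L) {
    stop_config("at least one reference gene must be configured")
  }
  if (is.null(names(expression))) {
    stop_validation("expression must be named by sample id")
  }
  assert_finite(expression, "planted expression")
  set.seed(seed)
  n <- length(expression)
  ct_goi <- intercept - expression + stats::rnorm(n, 0, noise_sd)
  ct_refs <- matrix(intercept +
                      stats::rnorm(n * length(reference_genes), 0, noise_sd),
                    nrow = length(reference_genes),
                    dimnames = list(reference_genes, names(expression)))
  values <- rbind(matrix(ct_goi, nrow = 1,
                         dimnames = list(goi, names(expression))),
                  ct_refs)
  expression_matrix(values, platform = "qpcr", scale = "ct")
}

#' Write a synthetic cohort to disk
#'
#' Tab-separated expression (features x samples), annotation and truth
#' tables, plus a YAML sidecar echoing the generator parameters and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop_validation("expected a synthetic_cohort")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expression,
                          file.path(dir, "expression.tsv"))
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- cohort$params
  p$tissue_mix <- as.list(p$tissue_mix)
  p$pde4d7_base <- as.list(p$pde4d7_base)
  yaml::write_yaml(unclass(p), file.path(dir, "params.yaml"))
  invisible(dir)
}
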