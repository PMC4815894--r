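# fusionstrat

Isoform-level expression biomarker analysis with expression-based fusion
calling, for transcriptomics of prostate cancer and similar settings where a
single transcript (here the phosphodiesterase isoform **PDE4D7**) is profiled
across heterogeneous platforms and related to a gene-fusion genotype
(**TMPRSS2-ERG**), tumour grade and time-to-recurrence outcomes.

The package is aimed at computational biologists who need the complete chain
— platform normalization, fusion-status estimation, group statistics,
ROC-derived cutoffs, survival stratification and regulatory-region overlap —
as tested, reusable functions rather than a one-off analysis script.

## What it computes

**Normalization.** Three platform dialects are harmonized onto one
normalized log2 scale:

* qPCR: `N = mean(Ct_ref) − Ct_goi` against a configurable reference-gene
  panel (higher N = higher expression; invariant under per-sample Ct shifts);
* exon arrays: isoform expression as the arithmetic mean of log2 probe-set
  intensities over an isoform→probe-set map (single-probe-set maps pass
  through unchanged);
* RNA-seq: `log2(TPM + 1)`.

**Fusion calling.** Fusion status is estimated from log2 ERG expression by
robust z-scores, `z = (x − median) / MAD` with raw MAD, calling `z > 3`
positive — ERG outliers mark samples in which the fusion has placed ERG
under an androgen-responsive promoter. A deterministic one-dimensional
two-medoid clustering (exhaustive over contiguous splits in sorted order)
is provided as a fallback for cohorts where the outlier assumption fails,
e.g. when fusion prevalence approaches half the reference pool.

**Group statistics.** Wilcoxon–Mann–Whitney comparisons (exact by full
permutation enumeration up to 200,000 label assignments, tie-corrected
normal approximation with continuity correction above), ROC curves, AUC as
the pair-counting probability (identically `U/(n_a n_b)`), DeLong 95% CI
and p-value against AUC = 0.5, and the cutoff maximizing
sensitivity + specificity.

**Survival.** Kaplan–Meier product-limit curves with medians, the log-rank
test, the hazard ratio from log-rank observed/expected counts (with a Cox
cross-check estimator), cutoff-stratified comparisons (low group =
expression strictly below the cutoff), a 24-month early/late recurrence
dichotomy and a 5-year-window with/without-event filter.

**Regulatory overlap.** BED-style 0-based half-open interval arithmetic:
flanking a gene region (e.g. ±50 kb) and counting overlapping ChIP-seq
peaks, with gap distances for near-miss peaks (e.g. < 200 bases).

**Synthetic cohorts.** `generate_cohort()` plants the full statistical
structure the analysis assumes — bimodal ERG with a set fusion prevalence,
a 2-fold biomarker elevation in fusion-positive tumours, a grade-dependent
decline confined to fusion-positive samples, and exponential recurrence
times whose log-hazard is linear in expression — so every stage is testable
against known truth without external data.

## Worked example

```r
library(fusionstrat)

cohort <- generate_cohort(cohort_params(n_samples = 500, seed = 1))
report <- run_pipeline(cohort$expression, cohort$annotation,
                       analysis_config(seed = 1))
print(report)
#> analysis_report: 500 samples, 160 fusion-positive
#>   7 group contrasts computed
#>   expression cutoff: 2.366
#> HR (high vs low) = 0.527 (95% CI 0.408-0.681); log-rank p = 7.74e-07
#>   median survival: low = 22.09958, high = 44.32556 months

subset(report$comparisons, group_b == "tumour_fusion_pos" &
                           group_a == "tumour_fusion_neg",
       c(median_a, median_b, p_value))
#>                   median_a median_b      p_value
#> fusion_neg_vs_pos  2.02174 2.988481 6.588357e-34
```

Fusion-positive tumours sit ~1 log2 unit (2-fold) above fusion-negative
ones; the ROC-derived expression cutoff splits the cohort into a
poor-prognosis low-expression group (median time to recurrence ~22 months)
and a protected high-expression group (~44 months, hazard ratio ≈ 0.53).

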