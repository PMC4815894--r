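---
title: "Methods: isoform biomarker stratification with expression-based fusion calling"
author: "fusionstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform biomarker stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionstrat)
```

This vignette documents the models, conventions and design choices behind
the package, in the spirit of a statistical-methods supplement. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis problem

A single transcript isoform (PDE4D7, a long isoform of phosphodiesterase
4D) is measured across cohorts profiled on three platforms — qPCR, exon
arrays and RNA-seq — and related to (i) the *TMPRSS2-ERG* gene fusion, a
prostate-cancer-specific rearrangement that places the ETS transcription
factor ERG under an androgen-responsive promoter, (ii) histological grade
(Gleason score) and (iii) time to biochemical or clinical recurrence after
primary treatment. All analyses are within-dataset: values from different
platforms are never pooled or quantile-aligned, mirroring the per-cohort
structure such studies report.

## Normalization

**qPCR.** `normalize_qpcr()` computes `N = mean(Ct_ref) − Ct_goi`. The sign
convention — subtracting the gene-of-interest Ct *from* the reference mean —
is chosen so that higher `N` means higher expression, which is required for
downstream conventions such as "normalized expression > 0" marking the
high-expression stratum. The formula is invariant under any additive shift
of a sample's Ct values, which is precisely what makes it comparable across
runs. Reference-gene panels are configuration, not code.

**Exon arrays.** `summarize_probesets()` averages log2 probe-set
intensities per isoform. The mean is taken on the log2 scale — averaging
`[2, 4, 6]` gives 4.0, not `log2((4+16+64)/3) ≈ 4.81` — and a
single-probe-set map passes values through unchanged, covering datasets
where only one probe set has usable signal. RMA processing of CEL files is
out of scope: the package consumes already-summarized probe-set tables.

**RNA-seq.** `transform_tpm()` uses `log2(TPM + 1)`. The pseudocount of 1
is the conventional choice; it maps TPM = 0 to 0 and keeps the transform
strictly increasing. TPM estimation itself is out of scope.

**Missing values** are never imputed; samples missing a required feature
are dropped with a warning naming the count.

## Fusion calling from ERG expression

The robust z-score caller computes `z = (x − median)/MAD` over a reference
pool and calls `z > 3` positive, with a *strict* inequality (a sample at
exactly 3 is negative). Two deliberate choices:

* **Raw MAD.** The median absolute deviation is used exactly as written in
  the robust z-score, without the 1.4826 normal-consistency factor; the
  factor is available behind `mad_consistency = TRUE` (which makes the
  threshold ~1.48× more stringent on normal data).
* **Reference pool.** Defaults to all samples of the dataset;
  `tumours_only` is offered since it is genuinely ambiguous whether normal
  adjacent tissue should contribute to the pooled median/MAD.

The caller's operating assumption is that fusion-positive samples are a
*minority*: the pooled median and MAD then track the fusion-negative
background and positives stand out as extreme outliers. As the positive
fraction approaches one half of the pool, the pooled median migrates into
the gap between the two ERG modes and the MAD inflates to the mode
separation; sensitivity collapses. This failure mode is pinned by a test
(an all-tumour pool at 50% prevalence) rather than hidden — in that regime
the two-medoid fallback is the right tool.

**Two-medoid fallback.** `call_fusion_pam()` performs k = 2 medoid
clustering of one-dimensional log2 ERG values. In one dimension the optimal
two-medoid partition under total absolute deviation is contiguous in sorted
order, so the global optimum is found by exhaustive search over the n − 1
contiguous splits with lower-median medoids — no random initialization, a
deterministic result, verified in tests against an exhaustive
all-medoid-pairs oracle. The cluster with the higher medoid is labelled
fusion-positive. (The clustering is plain unsupervised k-medoids; nothing
about it requires labels.)

## Group statistics

**Mann–Whitney.** The U statistic counts cross-group pairs with ties
weighted 1/2. The two-sided p-value is exact — full enumeration of label
assignments, valid under ties because midranks are recomputed per
assignment — whenever `choose(n_a + n_b, n_a) ≤ 200,000`, and a
tie-corrected normal approximation with continuity correction otherwise.
The enumeration bound is a compute/accuracy trade-off: it admits groups up
to ~10 + 10 while keeping the exact path below a second. No
multiple-testing correction is applied anywhere; reports state raw
p-values and the number of contrasts.

**ROC and AUC.** The AUC is computed as the pair-counting probability,
identically `U/(n_a n_b)` — an equality the suite asserts to 1e-12 as a
cross-module oracle, together with `AUC(s) + AUC(−s) = 1`. The 95% CI and
the p-value against 0.5 use the DeLong placement variance (cross-checked
against an independent implementation in the tests); Hanley–McNeil is
available behind a flag. For perfectly separated data the DeLong variance
is zero; the CI then degenerates to a point and p is reported as 0 — a
documented boundary rather than an error.

**Optimal cutoff.** `optimal_cutoff()` maximizes J = sensitivity +
specificity. Ties in J are broken toward higher specificity, then toward
the lower threshold, making the choice deterministic. The returned cutoff
is the midpoint of the gap between the adjacent distinct scores separated
by the optimal threshold, so it falls strictly between the groups when
they are separated. A midpoint does not commute exactly with nonlinear
monotone transforms of the scores, so the invariance the package promises
(and tests) is the meaningful one: the *induced group assignment* and the
sensitivity/specificity/J at the cutoff are invariant under strictly
monotone transforms. Downstream, group membership uses `score < cutoff`
strictly for the low/poor-prognosis group, so a sample exactly at the
cutoff is "high".

## Survival analysis

Kaplan–Meier estimation and the log-rank test are computed through the
`survival` package (`survfit`/`survdiff`); the surrounding definitions are
this package's contract. The curve median is the earliest event time at
which survival drops to 0.5 or below, `NA` if never reached. With no
censoring the product-limit estimate equals the empirical survival
function exactly (up to floating-point rounding of algebraically equal
products), which the suite asserts.

**Hazard ratio.** The default estimator is the log-rank observed/expected
ratio `HR = (O₂/E₂)/(O₁/E₁)` with the Tsiatis-style log-scale CI
`se(log HR) = √(1/E₁ + 1/E₂)` — the statistic KM-module reports
conventionally print next to the log-rank p. This estimator is *attenuated
toward 1 for strong effects*, a fixed bias that does not vanish with sample
size (for a true HR of 0.3 with full follow-up it converges near 0.38).
For that reason `hazard_ratio()` also offers `estimator = "cox"`, a
single-covariate Cox fit, which is consistent; the acceptance suite checks
the recovery window on the O/E path and error decay with n on the Cox
path. Group order is fixed as low-expression (reference) then
high-expression, so HR < 1 always reads "high expression is protective".

**Horizons.** Time is in months throughout. The recurrence dichotomy
splits events at 24 months, with an event at exactly 24 months classified
"late" (the boundary is otherwise undefined by the strict `<24`/`>24`
phrasing in common use). The with/without-event comparison within a 5-year
window keeps a sample only if its window status is defined: event at ≤ 60
months, or followed (event-free) to ≥ 60 months — a sample whose *event*
falls beyond the horizon is event-free *within* the window and is kept in
the no-event group; samples censored early are dropped with a logged
count. Under the generator's administrative censoring at 60 months the
beyond-horizon-event case cannot arise, but real cohorts have longer
follow-up.

## Genomic overlap

All interval arithmetic is BED-style 0-based half-open; touching intervals
do not overlap. GFF-style 1-based inputs must be converted at the reading
boundary (the BED reader/writer uses `rtracklayer`). `flank_region()`
extends both sides, clipping only at zero — chromosome lengths are not
assumed. Strand is ignored (ChIP-seq peaks are unstranded). Non-overlapping
peaks get a gap distance (0 for touching), so near-miss peaks within, say,
200 bases of a promoter can be flagged. Coordinate lift-over between
assemblies is consumed, not implemented; the caller is responsible for a
consistent assembly.

## The synthetic cohort generator

`generate_cohort()` plants exactly the structure the analysis assumes, so
that every downstream stage can be tested against known truth:

* **Tissue mix** (default 20% NAT / 80% tumour) with deterministic class
  counts (largest-fractional-part allocation), so stratum sizes do not
  fluctuate across seeds.
* **Fusion prevalence** 0.4 of tumours by default. One half is the
  documented breakdown point of outlier-based calling, and reported
  prevalences in prostate cancer are near but below one half once normal
  tissue enters the pool; 0.4 keeps the generator inside the caller's
  operating regime while the breakdown is exercised explicitly in tests.
* **ERG**: fusion-negative samples draw from N(0, 0.5), positive from
  N(6, 1) on the log2 scale — a separation typical of expression-outlier
  fusion cohorts, and the regime the caller's documented recovery targets
  (sensitivity and specificity ≥ 0.95) refer to.
* **Biomarker**: `base(tissue) + 1.0·[fusion+] +
  grade_effect·(g − 2.5)·[fusion+] + N(0, 0.5)` with `grade_effect = −0.5`
  per Gleason-group step. The fusion effect of +1 log2 unit is a 2-fold
  elevation. The grade term is *centered at the mean group index* (2.5
  under the uniform grade distribution): this keeps `fusion_effect` equal
  to the elevation of the typical-grade fusion-positive tumour, so the
  planted 2-fold elevation and the grade-dependent decline hold
  simultaneously rather than cancelling; low-vs-high-grade contrasts are
  unaffected by the centering.
* **Outcome**: exponential recurrence times with hazard
  `0.08 · exp(−0.5 · expression)` per month, censored by
  U(0, 120 months) and administratively at 60 months (a 5-year follow-up
  window). A constant baseline hazard is the simplest model consistent
  with single-number hazard-ratio summaries; a Weibull shape would be the
  natural extension.

What the generator does **not** emulate: batch and platform artefacts,
probe-level noise structure, copy-number or mutation co-drivers,
multi-gene signatures, non-proportional hazards, and read-level data.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to real-data artefacts.

The qPCR plate generator inverts the normalization: the gene-of-interest
Ct is `intercept − expression + noise` (each doubling of expression lowers
Ct by one cycle) and reference Cts are drawn around the stable intercept,
so the noise-free round trip through `normalize_qpcr_matrix()` is exact —
a property the suite asserts, alongside recovery correlation > 0.99 at a
realistic 0.1-cycle noise.

## Simulation scales and numerical conventions

The statistical acceptance checks run at the scales their claims name:
100 seeds at n = 500 for fusion-caller recovery and the end-to-end
directional findings; 1000 null cohorts at n = 200 for log-rank size
(rejection rate 5% ± 3%); 100 seeds per arm size for hazard-ratio
recovery at n = 50/200/800; 200 random instances for the AUC/U
equivalence at 1e-12; 1000 random interval sets against the brute-force
overlap oracle. These sizes were chosen so each claim's Monte-Carlo error
is well below the margin it asserts while the whole suite stays in the
minutes range on one CPU.

Numerical conventions worth knowing: z-score and cutoff ties are resolved
by documented deterministic rules (strict `> 3`; higher specificity then
lower threshold); exact-vs-approximate Mann–Whitney agreement is asserted
within 10% relative with a 0.005 absolute floor, because the normal
approximation's *relative* tail error at enumerable sizes is irreducible
however it is implemented; empty strata, zero MAD, all-censored and
single-class inputs raise typed conditions (`validation`, `config`,
`degenerate`) that the CLI maps to distinct exit codes (2 and 3).

## Known limitations

* Cross-platform values are deliberately never pooled; there is no
  meta-analysis layer.
* The O/E hazard ratio should not be read as an unbiased effect estimate
  for strong effects; use the Cox estimator when the magnitude matters.
* Fusion calling from expression cannot distinguish ERG overexpression by
  fusion from other causes, and ETV1/ETV4 rearrangements are annotation
  passthrough only.
* Peak/region overlap assumes both inputs are on the same assembly; the
  package records but cannot verify assembly labels.
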