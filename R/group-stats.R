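#' Wilcoxon-Mann-Whitney two-group comparison
#'
#' Rank-sum comparison of two groups of expression values. The U statistic
#' counts, over all \eqn{n_a n_b} cross-group pairs, how often a value from
#' group A exceeds one from group B (ties count 1/2). The two-sided p-value
#' is computed by full permutation enumeration of the group labels whenever
#' \eqn{\binom{n_a+n_b}{n_a} \le} `exact_limit` (exact even in the presence
#' of ties); above that, a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @param label_a,label_b group labels carried into the result.
#' @param exact_limit enumerate exactly when the number of label assignments
#'   is at most this (default 200000).
#' @return a `group_comparison` list: `group_a_label`, `group_b_label`, `n_a`,
#'   `n_b`, `median_a`, `median_b`, `U` (for group A), `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
#'
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1, by enumeration
mann_whitney <- function(group_a, group_b, label_a = "A", label_b = "B",
                         exact_limit = 2e5) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_validation("both groups must be non-empty")
  }
  assert_finite(group_a, "group A values")
  assert_finite(group_b, "group B values")
  n_a <- length(group_a)
  n_b <- length(group_b)
  x <- c(group_a, group_b)
  n <- n_a + n_b

  u_stat <- function(idx_a) {
    r <- rank(x)
    sum(r[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  u_obs <- u_stat(seq_len(n_a))
  mu <- n_a * n_b / 2

  all_tied <- length(unique(x)) == 1L
  if (all_tied) {
    warning("all values tied across both groups; p = 1")
    p <- 1
    method <- "degenerate"
  } else if (choose(n, n_a) <= exact_limit) {
    # exact two-sided p by enumerating every assignment of labels;
    # valid with ties because U is computed from midranks each time
    combos <- utils::combn(n, n_a)
    r <- rank(x)
    offset <- n_a * (n_a + 1) / 2
    u_all <- colSums(matrix(r[combos], nrow = n_a)) - offset
    dev_obs <- abs(u_obs - mu)
    p <- mean(abs(u_all - mu) >= dev_obs - 1e-9)
    method <- "exact"
  } else {
    r <- rank(x)
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    cc <- 0.5 * sign(u_obs - mu)
    z <- (u_obs - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }

  structure(list(group_a_label = label_a, group_b_label = label_b,
                 n_a = n_a, n_b = n_b,
                 median_a = stats::median(group_a),
                 median_b = stats::median(group_b),
                 U = u_obs, p_value = p, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney: %s (n=%d, median=%.3g) vs %s (n=%d, median=%.3g)\n",
              x$group_a_label, x$n_a, x$median_a,
              x$group_b_label, x$n_b, x$median_b))
  cat(sprintf("  U = %.1f, two-sided p = %.4g (%s)\n", x$U, x$p_value, x$method))
  invisible(x)
}

#' ROC curve over all score thresholds
#'
#' One operating point per distinct score value plus the two trivial
#' endpoints. At threshold t a sample is predicted positive when
#' `score >= t` (direction `">"`) or `score <= t` (direction `"<"`);
#' `direction = "auto"` picks the orientation whose AUC is >= 0.5 for the
#' stated positive class, so a marker can be used without first knowing
#' whether high values indicate the positive class.
#'
#' @param scores numeric marker values.
#' @param labels positive-class indicator: logical, or 0/1 numeric.
#' @param direction `"auto"`, `">"` (higher score more positive) or `"<"`.
#' @return a `roc_curve` list: `thresholds` (descending), `sensitivity`,
#'   `specificity`, `direction`, `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  assert_finite(scores, "scores")
  if (length(scores) != length(labels)) {
    stop_validation("scores and labels must have equal length")
  }
  if (length(unique(labels)) < 2L) {
    stop_validation("both classes must be present")
  }
  if (direction == "auto") {
    direction <- if (pair_auc(scores, labels) >= 0.5) ">" else "<"
  }
  s <- if (direction == ">") scores else -scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pos <- s[labels == 1L]
  neg <- s[labels == 0L]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  thresholds <- if (direction == ">") thr else -thr
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, direction = direction,
                 scores = scores, labels = labels),
            class = "roc_curve")
}

#' Area under the ROC curve with DeLong inference
#'
#' The AUC is computed as the Mann-Whitney pair-counting probability that a
#' positive-class sample scores higher than a negative-class one, ties
#' counting 1/2 — identically `U / (n_a n_b)` of [mann_whitney()] on the same
#' data. The orientation is taken as given (higher score = more positive);
#' an anti-discriminating marker therefore yields AUC < 0.5, and
#' `AUC(scores) + AUC(-scores) = 1` exactly. The 95% CI and the p-value
#' against AUC = 0.5 use the DeLong (1988) placement variance by default;
#' the Hanley-McNeil variance is available as an alternative.
#'
#' @param scores numeric marker values (higher = more indicative of the
#'   positive class).
#' @param labels positive-class indicator: logical, or 0/1 numeric.
#' @param conf_level CI coverage (default 0.95).
#' @param var_method `"delong"` (default) or `"hanley"`.
#' @return a `roc_summary` list: `auc`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `n_pos`, `n_neg`, `var_method`.
#' @export
#'
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc  # 0.75
roc_auc <- function(scores, labels, conf_level = 0.95,
                    var_method = c("delong", "hanley")) {
  var_method <- match.arg(var_method)
  labels <- as_binary_labels(labels)
  assert_finite(scores, "scores")
  if (length(unique(labels)) < 2L) {
    stop_validation("both classes must be present")
  }
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  auc <- pair_auc(scores, labels)

  if (var_method == "delong") {
    # placement values: V10 over positives, V01 over negatives
    v10 <- vapply(pos, function(p) (sum(p > neg) + 0.5 * sum(p == neg)) / n,
                  numeric(1))
    v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / m,
                  numeric(1))
    var_auc <- stats::var(v10) / m + stats::var(v01) / n
    if (m == 1L) var_auc <- stats::var(v01) / n
    if (n == 1L) var_auc <- stats::var(v10) / m
    if (m == 1L && n == 1L) var_auc <- 0
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    var_auc <- (auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n - 1) * (q2 - auc^2)) / (m * n)
  }
  var_auc <- max(var_auc, 0)
  se <- sqrt(var_auc)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se)
       else if (auc == 0.5) 1 else 0
  structure(list(auc = auc, se = se, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, n_pos = m, n_neg = n, var_method = var_method),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), p vs 0.5 = %.3g [%s; %d pos / %d neg]\n",
              x$auc, x$ci_low, x$ci_high, x$p_value, x$var_method,
              x$n_pos, x$n_neg))
  invisible(x)
}

# pair-counting AUC, ties 1/2: P(score_pos > score_neg) + P(=)/2.
# Computed from midranks in O(n log n).
pair_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  m <- sum(labels == 1L)
  n <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

#' Optimal ROC cutoff by maximum sensitivity + specificity
#'
#' Returns the operating point maximizing J = sensitivity + specificity
#' (the Youden-type criterion) and an actionable cutoff value: the midpoint
#' of the gap between the adjacent distinct scores that the optimal
#' threshold separates, so the cutoff falls strictly between the two groups
#' when they are separated. Ties in J are broken toward higher specificity,
#' then toward the lower threshold. Group membership downstream uses
#' `score < cutoff` for the low/poor-prognosis group (strict).
#'
#' @param curve a [roc_curve()].
#' @return a `cutoff_result` list: `cutoff`, `sensitivity`, `specificity`,
#'   `J`, `direction`.
#' @export
optimal_cutoff <- function(curve) {
  if (!inherits(curve, "roc_curve")) stop_validation("expected a roc_curve")
  J <- curve$sensitivity + curve$specificity
  if (max(J) <= 1 + 1e-12) {
    warning("degenerate (diagonal) ROC curve; returning midpoint threshold")
    rng <- range(curve$scores)
    return(structure(list(cutoff = mean(rng), sensitivity = NA_real_,
                          specificity = NA_real_, J = 1,
                          direction = curve$direction),
                     class = "cutoff_result"))
  }
  best <- which(J >= max(J) - 1e-12)
  best <- best[order(-curve$specificity[best],
                     if (curve$direction == ">") curve$thresholds[best]
                     else -curve$thresholds[best])]
  k <- best[1L]
  thr <- curve$thresholds[k]
  # oriented, ascending distinct scores; the chosen threshold classifies
  # "score >= thr" positive (direction ">"), so any cutoff in the gap below
  # thr induces the same split — report the gap midpoint
  s <- sort(unique(if (curve$direction == ">") curve$scores
                   else -curve$scores))
  t_or <- if (curve$direction == ">") thr else -thr
  cutoff <- if (!is.finite(t_or)) {
    if (t_or > 0) max(s) + 1 else min(s) - 1
  } else {
    below <- s[s < t_or]
    if (length(below)) (t_or + max(below)) / 2 else t_or - 1
  }
  if (curve$direction == "<") cutoff <- -cutoff
  structure(list(cutoff = cutoff,
                 sensitivity = curve$sensitivity[k],
                 specificity = curve$specificity[k],
                 J = J[k], direction = curve$direction),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff = %.4g (direction %s): sens %.3f, spec %.3f, J = %.3f\n",
              x$cutoff, x$direction, x$sensitivity, x$specificity, x$J))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop_validation("numeric labels must be 0/1")
    }
    return(as.integer(labels))
  }
  u <- sort(unique(labels))
  if (length(u) > 2L) stop_validation("labels must be binary")
  as.integer(labels == u[length(u)])
}
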