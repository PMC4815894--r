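# Independent brute-force oracles used across the suite. Each is written as
# the naive definition of the quantity, deliberately ignoring how the
# package computes it.

# pair-counting AUC: P(score_pos > score_neg) + P(tie)/2, explicit loop
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Mann-Whitney U for group a, explicit pair loop with half ties
oracle_u <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot
}

# exact two-sided permutation p for the U statistic
oracle_mw_exact_p <- function(a, b) {
  x <- c(a, b)
  n_a <- length(a)
  combos <- utils::combn(length(x), n_a)
  mu <- n_a * length(b) / 2
  u_obs <- oracle_u(a, b)
  u_all <- apply(combos, 2L, function(idx) oracle_u(x[idx], x[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# half-open interval overlap count, explicit pairwise test
oracle_overlap_count <- function(peaks, region) {
  n <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] == region$chrom &&
        peaks$start[i] < region$end &&
        region$start < peaks$end[i]) {
      n <- n + 1L
    }
  }
  n
}

# optimal 1-D 2-medoid partition by exhaustive search over all medoid pairs
oracle_pam2 <- function(x) {
  n <- length(x)
  best_cost <- Inf
  best_assign <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d1 <- abs(x - x[i])
    d2 <- abs(x - x[j])
    assign_high <- ifelse(d2 < d1, TRUE, FALSE)  # ties to medoid i
    cost <- sum(pmin(d1, d2))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      hi <- if (x[j] > x[i]) assign_high else !assign_high
      best_assign <- hi
    }
  }
  list(cost = best_cost, positive = best_assign)
}

# log-rank chi-square from first principles: hypergeometric moments at each
# distinct event time
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g == 1L)
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (o_minus_e)^2 / v
}

# empirical survival function (no censoring): P(T > t)
oracle_empirical_surv <- function(times, t) mean(times > t)
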