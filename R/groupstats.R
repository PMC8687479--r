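#' Classify a subject as resilient or vulnerable
#'
#' A subject is resilient if every pandemic PHQ-4 total is lower than or
#' equal to the pre-pandemic total, and vulnerable if any pandemic timepoint
#' exceeds it. Classification uses whatever pandemic timepoints the subject
#' completed (1 to 3).
#'
#' @param phq_pre Pre-pandemic PHQ-4 total, integer 0..12.
#' @param phq_pandemic Integer vector of 1-3 pandemic PHQ-4 totals, 0..12.
#' @param subject_id Optional id carried through to the result.
#' @return List with `subject_id`, `label` (`"resilient"` or
#'   `"vulnerable"`), and `n_pandemic_timepoints`.
#' @export
#' @examples
#' classify_resilience(2, c(2, 1, 2))$label  # "resilient"
#' classify_resilience(2, c(1, 3, 0))$label  # "vulnerable"
classify_resilience <- function(phq_pre, phq_pandemic, subject_id = NULL) {
  if (length(phq_pandemic) < 1L || length(phq_pandemic) > 3L)
    stopf("phq_pandemic must contain 1-3 scores")
  if (phq_pre < 0 || phq_pre > 12 || any(phq_pandemic < 0 | phq_pandemic > 12))
    stopf("PHQ-4 totals must lie in 0..12")
  list(subject_id = subject_id,
       label = if (all(phq_pandemic <= phq_pre)) "resilient" else "vulnerable",
       n_pandemic_timepoints = length(phq_pandemic))
}

#' Classify every subject in a cohort table
#'
#' @param cohort Cohort data.frame (see [read_cohort()]).
#' @return data.frame: subject_id, label, n_pandemic_timepoints.
#' @export
classify_cohort <- function(cohort) {
  res <- mapply(function(id, pre, pand) classify_resilience(pre, pand, id),
                cohort$subject_id, cohort$phq_pre, cohort$phq_pandemic,
                SIMPLIFY = FALSE)
  data.frame(
    subject_id = vapply(res, `[[`, "", "subject_id"),
    label = vapply(res, `[[`, "", "label"),
    n_pandemic_timepoints = vapply(res, `[[`, 0L, "n_pandemic_timepoints"),
    stringsAsFactors = FALSE)
}

#' Mean pandemic PHQ-4 score
#'
#' Arithmetic mean of the completed pandemic questionnaires' totals — the
#' response variable of the regression stage.
#'
#' @param phq_pandemic Non-empty vector of pandemic PHQ-4 totals.
#' @return Scalar mean.
#' @export
mean_pandemic_score <- function(phq_pandemic) {
  if (length(phq_pandemic) == 0L) stopf("no pandemic PHQ-4 scores")
  mean(phq_pandemic)
}

#' PHQ-2 / GAD-2 subscale screening
#'
#' On each two-item subscale (range 0..6) a score of 3 or more is positive
#' for screening purposes.
#'
#' @param subscale_score Integer 0..6.
#' @return Logical.
#' @export
screen_positive <- function(subscale_score) {
  if (any(subscale_score < 0 | subscale_score > 6) ||
      any(subscale_score != round(subscale_score)))
    stopf("subscale score must be an integer in 0..6")
  subscale_score >= 3
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties, with a two-sided p-value
#' from the t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values in x or y")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stopf("Spearman correlation undefined for a constant vector")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# Find maximal runs of TRUE; returns data.frame(start_idx, end_idx).
find_runs <- function(sig) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

# Group-A membership indicator matrix for the permutation ensemble:
# B x n logical. exact = all choose(n, nA) assignments; otherwise B random
# label scramblings (each a uniform draw over assignments).
perm_matrix <- function(n, n_a, n_perm, exact) {
  if (exact) {
    combos <- utils::combn(n, n_a)
    P <- matrix(FALSE, ncol(combos), n)
    for (b in seq_len(ncol(combos))) P[b, combos[, b]] <- TRUE
  } else {
    P <- matrix(FALSE, n_perm, n)
    for (b in seq_len(n_perm)) P[b, sample.int(n, n_a)] <- TRUE
  }
  P
}

#' Cluster-corrected permutation test on evoked time-series
#'
#' Compares two groups of response series pointwise within a time window and
#' corrects for multiple comparisons by cluster size and magnitude against a
#' permutation null.
#'
#' The observed statistic is the pointwise difference of group means
#' `d(t) = mean_A(t) - mean_B(t)`. Group labels are scrambled `n_perm` times;
#' the two-sided pointwise p-value is
#' `(#\{perm: |d_perm(t)| >= |d(t)|\} + 1) / (n_perm + 1)`. Clusters are
#' maximal runs of contiguous samples with `p(t) < alpha`; a cluster's size
#' is its number of timepoints and its magnitude (mass) is `sum |d(t)|` over
#' its samples. The same clustering is applied to every permutation's own
#' pointwise p-values (ranked within the full permutation ensemble); under
#' `null_mode = "max_per_perm"` each permutation contributes its maximum
#' cluster size and maximum magnitude (0 if it has no cluster) — the
#' standard FWER-controlling max-statistic construction — while
#' `null_mode = "pooled"` collects every null cluster. A cluster survives if
#' its size exceeds the `percentile`% of the null sizes *and* its magnitude
#' exceeds the `percentile`% of the null magnitudes.
#'
#' @param group_a,group_b Lists of `response_series` (>= 2 each) on identical
#'   time axes, e.g. resilient vs vulnerable subjects' local z-series.
#' @param window Analysis window in ms, default `c(15, 400)`.
#' @param n_perm Number of permutations (default 1000). Fewer than 100
#'   triggers a warning.
#' @param alpha Pointwise significance threshold.
#' @param percentile Null percentile (default 95) a cluster must exceed on
#'   both size and magnitude.
#' @param null_mode `"max_per_perm"` or `"pooled"`.
#' @param seed Optional integer; fixes the permutation stream.
#' @param exact Enumerate all `choose(n, n_a)` label assignments instead of
#'   Monte-Carlo sampling (small groups only). Pointwise p-values are then
#'   exact proportions over the full assignment set.
#' @return Object of class `cluster_test`: `diff`, `pointwise_p`, `time_ms`,
#'   `clusters` (data.frame with start_ms, end_ms, size, magnitude,
#'   surviving), `surviving` (the surviving subset), `null_size`,
#'   `null_magnitude`, `n_perm`, `alpha`, `percentile`, `null_mode`, `seed`,
#'   and the group sizes.
#' @export
cluster_permutation_test <- function(group_a, group_b, window = c(15, 400),
                                     n_perm = 1000, alpha = 0.05,
                                     percentile = 95,
                                     null_mode = c("max_per_perm", "pooled"),
                                     seed = NULL, exact = FALSE) {
  null_mode <- match.arg(null_mode)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("each group needs at least 2 series")
  if (!exact && n_perm < 100)
    warning("n_perm < 100: permutation p-values will be very coarse")
  tt <- group_a[[1]]$time_ms
  all_series <- c(group_a, group_b)
  for (s in all_series)
    if (length(s$time_ms) != length(tt) || any(abs(s$time_ms - tt) > 1e-6))
      stopf("all series must share one time axis")
  idx <- window_index(tt, window)
  tw <- tt[idx]
  X <- t(vapply(all_series, function(s) s$values[idx], numeric(length(idx))))
  n_a <- length(group_a)
  n_b <- length(group_b)
  n <- n_a + n_b
  d_obs <- colMeans(X[seq_len(n_a), , drop = FALSE]) -
    colMeans(X[n_a + seq_len(n_b), , drop = FALSE])

  with_seed(seed, {
    P <- perm_matrix(n, n_a, n_perm, exact)
    B <- nrow(P)
    storage.mode(P) <- "double"
    D <- (P %*% X) / n_a - ((1 - P) %*% X) / n_b   # B x T permutation diffs
    # round to 12 significant digits so exact ties (same assignment, other
    # summation order) are counted as ties in the rank comparisons
    absD <- signif(abs(D), 12)
    abs_obs <- signif(abs(d_obs), 12)

    cnt <- colSums(absD >= rep(abs_obs, each = B))
    pointwise_p <- if (exact) cnt / B else (cnt + 1) / (B + 1)

    # Pointwise null p-values for each permutation, ranked within the
    # ensemble: p_b(t) = #{b': |D[b',t]| >= |D[b,t]|} / B.
    Pnull <- (B - apply(absD, 2, rank, ties.method = "min") + 1) / B

    cluster_stats <- function(sig, mags) {
      runs <- find_runs(sig)
      if (nrow(runs) == 0L)
        return(data.frame(start_idx = integer(0), end_idx = integer(0),
                          size = integer(0), magnitude = numeric(0)))
      runs$size <- runs$end_idx - runs$start_idx + 1L
      runs$magnitude <- vapply(seq_len(nrow(runs)), function(k)
        sum(mags[runs$start_idx[k]:runs$end_idx[k]]), 0)
      runs
    }

    null_size <- numeric(0)
    null_magnitude <- numeric(0)
    if (null_mode == "max_per_perm") {
      null_size <- numeric(B)
      null_magnitude <- numeric(B)
      for (b in seq_len(B)) {
        cl <- cluster_stats(Pnull[b, ] < alpha, absD[b, ])
        null_size[b] <- if (nrow(cl)) max(cl$size) else 0
        null_magnitude[b] <- if (nrow(cl)) max(cl$magnitude) else 0
      }
    } else {
      for (b in seq_len(B)) {
        cl <- cluster_stats(Pnull[b, ] < alpha, absD[b, ])
        null_size <- c(null_size, cl$size)
        null_magnitude <- c(null_magnitude, cl$magnitude)
      }
      if (length(null_size) == 0L) {
        null_size <- 0
        null_magnitude <- 0
      }
    }

    obs_cl <- cluster_stats(pointwise_p < alpha, abs_obs)
    exceeds <- function(x, null_vals) mean(null_vals < x) >= percentile / 100
    obs_cl$surviving <- vapply(seq_len(nrow(obs_cl)), function(k)
      exceeds(obs_cl$size[k], null_size) &&
        exceeds(obs_cl$magnitude[k], null_magnitude), TRUE)
    clusters <- data.frame(start_ms = tw[obs_cl$start_idx],
                           end_ms = tw[obs_cl$end_idx],
                           size = obs_cl$size, magnitude = obs_cl$magnitude,
                           surviving = obs_cl$surviving)

    structure(list(diff = d_obs, pointwise_p = pointwise_p, time_ms = tw,
                   clusters = clusters,
                   surviving = clusters[clusters$surviving, , drop = FALSE],
                   null_size = null_size, null_magnitude = null_magnitude,
                   n_perm = B, alpha = alpha, percentile = percentile,
                   null_mode = null_mode, seed = seed, exact = exact,
                   n_a = n_a, n_b = n_b),
              class = "cluster_test")
  })
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d vs %d series, %d perms (%s), alpha %.3g\n",
              x$n_a, x$n_b, x$n_perm, x$null_mode, x$alpha))
  if (nrow(x$clusters) == 0L) {
    cat("  no pointwise-significant clusters\n")
  } else {
    for (k in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %g..%g ms: size %d, magnitude %.3g%s\n",
                  x$clusters$start_ms[k], x$clusters$end_ms[k],
                  x$clusters$size[k], x$clusters$magnitude[k],
                  if (x$clusters$surviving[k]) "  [survives]" else ""))
  }
  invisible(x)
}
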