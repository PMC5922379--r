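#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test with the two-sided p-value defined by the
#' sum-of-small-probabilities rule: the sum of hypergeometric
#' probabilities of every table with the observed margins whose
#' probability does not exceed the observed table's (up to a small
#' relative tolerance for floating-point ties). This is the convention
#' of [stats::fisher.test()], to which the computation is delegated.
#' An empty row or column margin yields p = 1 with a warning.
#'
#' @param counts 2x2 matrix of non-negative integer counts
#'   (rows = clinical category, columns = marker high/low).
#' @return two-sided p-value.
#' @examples
#' fisher_exact_two_sided(matrix(c(12, 0, 12, 7), nrow = 2))
#' @export
fisher_exact_two_sided <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("'counts' must be a 2x2 table", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1) stop("empty table", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("empty margin; p = 1 by convention", call. = FALSE)
    return(1)
  }
  fisher.test(counts)$p.value
}

#' Two-sample t-test
#'
#' Pooled-variance Student t by default (`pooled = FALSE` gives
#' Welch). When both samples are constant with equal means the
#' statistic is 0 and p = 1; constant samples with different means are
#' a degenerate-variance error.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param pooled use the pooled-variance statistic (default TRUE).
#' @return list: `statistic` (t), `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2L, p_value = 1))
    stop("degenerate variance: both samples constant with different means",
         call. = FALSE)
  }
  fit <- t.test(x, y, var.equal = pooled)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences equal to zero are dropped. For up to 25 non-zero pairs
#' the two-sided p-value is exact: the sign-flip null distribution of
#' the positive-rank sum (midranks for tied absolute differences) is
#' enumerated by generating-function convolution over all 2^n sign
#' assignments. Above 25 pairs the normal approximation with
#' continuity correction of [stats::wilcox.test()] is used.
#'
#' @param x,y paired numeric samples of equal length.
#' @return list: `statistic` (V, sum of positive ranks), `n_pairs`
#'   (non-zero pairs used), `p_value`, `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  exact <- n <= 25L
  if (exact) {
    # distribution of the positive-rank sum over the 2^n sign flips:
    # polynomial product of (1 + z^{2 r_i}) on doubled midranks
    w <- as.integer(round(2 * r))
    dist <- c(1, numeric(sum(w)))
    for (wi in w) dist <- dist + c(numeric(wi), dist)[seq_along(dist)]
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * v))
    p_lo <- sum(dist[seq_len(v2 + 1L)])              # P(2V <= v2)
    p_hi <- sum(dist[(v2 + 1L):length(dist)])        # P(2V >= v2)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  }
  list(statistic = v, n_pairs = n, p_value = p, exact = exact)
}

#' Optimal cutpoint for a percent-positive IHC marker
#'
#' Runs [maxstat_cutpoint()] on percent-positive tumor-cell values
#' (0-100) against a survival endpoint and additionally reports the
#' plain two-group log-rank p-value of the dichotomy at the selected
#' cutoff (the selection-adjusted `p_approx` is always at least as
#' large).
#'
#' @param percent_positive values in \[0, 100\].
#' @param times,events right-censored follow-up.
#' @param minprop,maxprop cutpoint window as in [maxstat_cutpoint()].
#' @return A `maxstat_result` with an extra `logrank_p` field.
#' @export
ihc_cutpoint <- function(percent_positive, times, events,
                         minprop = 0.1, maxprop = 1 - minprop) {
  if (any(!is.finite(percent_positive)) || any(percent_positive < 0) ||
      any(percent_positive > 100))
    stop("percent-positive values must lie in [0, 100]", call. = FALSE)
  res <- maxstat_cutpoint(percent_positive, times, events, minprop, maxprop)
  res$logrank_p <- logrank_test(times, events,
                                percent_positive > res$cutpoint)$p_value
  res
}
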