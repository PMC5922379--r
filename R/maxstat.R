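#' Log-rank scores for right-censored data
#'
#' Per-patient linear rank scores `a_i = delta_i - Lambda(t_i)` where
#' `Lambda` is the Nelson-Aalen cumulative hazard evaluated at the
#' patient's own time (events at `t_i` included). These are the scores
#' whose partial sums over a dichotomizing covariate give the log-rank
#' linear statistic; without ties they sum to zero exactly.
#'
#' @param times,events right-censored follow-up as in [kaplan_meier()].
#' @return numeric vector of scores, same order as the input.
#' @export
logrank_scores <- function(times, events) {
  check_surv_input(times, events)
  if (length(times) < 2L) stop("need at least 2 observations", call. = FALSE)
  ut <- sort(unique(times[events == 1]))
  if (!length(ut)) return(numeric(length(times)))
  d <- vapply(ut, function(u) sum(events[times == u]), 0)
  r <- vapply(ut, function(u) sum(times >= u), 0)
  Lam <- cumsum(d / r)
  # Lambda at each subject's own time (step function, right-continuous)
  idx <- findInterval(times, ut)
  events - c(0, Lam)[idx + 1L]
}

#' Selection-adjusted p-value for a maximally selected statistic
#'
#' Approximates `P(sup |B(t)/sqrt(t(1-t))| > b)` for a Brownian bridge
#' B over the quantile window `(q1, q2)` actually spanned by the
#' candidate cutpoints (an improved-Bonferroni bound of the
#' Miller-Siegmund type):
#' `p = 4 phi(b)/b + phi(b) (b - 1/b) log[ q2(1-q1) / (q1(1-q2)) ]`,
#' clamped to 1 for `b <= 1`.
#'
#' @param b standardized maximum statistic, `b >= 0`.
#' @param q1,q2 quantile window, `0 < q1 < q2 < 1`.
#' @return approximate upper-tail p-value in \[0, 1\].
#' @export
maxstat_pvalue <- function(b, q1, q2) {
  if (!is.finite(b) || b < 0) stop("'b' must be >= 0", call. = FALSE)
  if (!is.finite(q1) || !is.finite(q2) || q1 <= 0 || q2 >= 1 || q1 >= q2)
    stop("invalid quantile window: need 0 < q1 < q2 < 1", call. = FALSE)
  if (b <= 1) return(1)
  db <- dnorm(b)
  min(1, 4 * db / b + db * (b - 1 / b) * log(q2 * (1 - q1) / (q1 * (1 - q2))))
}

# Standardized partial-sum statistics at every candidate cutpoint.
# Returns the per-candidate |T_std| plus bookkeeping shared by the
# observed scan and the permutation oracle.
maxstat_scan <- function(x, scores, minprop, maxprop) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  # candidates: midpoints between consecutive distinct ordered values
  last_of_block <- which(diff(xs) > 0)
  if (!length(last_of_block)) stop("all marker values are equal", call. = FALSE)
  prop <- last_of_block / n
  keep <- prop >= minprop & prop <= maxprop
  if (sum(keep) < 2L)
    stop("fewer than 2 candidate cutpoints inside the quantile window", call. = FALSE)
  m <- last_of_block[keep]
  cuts <- (xs[m] + xs[m + 1L]) / 2
  abar <- mean(scores)
  ssq <- sum((scores - abar)^2)
  v <- m * (n - m) / (n * (n - 1)) * ssq
  list(order = o, m = m, cuts = cuts, abar = abar, sd = sqrt(v),
       q1 = min(m) / n, q2 = max(m) / n, n = n)
}

scan_statistics <- function(scan, scores) {
  Tm <- cumsum(scores[scan$order])[scan$m]
  (Tm - scan$m * scan$abar) / scan$sd
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Scans every candidate cutpoint mu (midpoints between consecutive
#' distinct marker values whose low-side proportion lies within
#' `[minprop, maxprop]`), forms the log-rank-score partial sum
#' `T(mu) = sum_{x_i <= mu} a_i`, standardizes it by its permutation
#' mean and variance, and returns the cutpoint maximizing `|T_std|`
#' (smallest mu on ties) with a selection-adjusted p-value from
#' [maxstat_pvalue()]. Both the statistic and the cutpoint's quantile
#' position are invariant under strictly monotone transforms of the
#' marker.
#'
#' @param x continuous marker (at least 3 distinct values inside the
#'   window).
#' @param times,events right-censored follow-up.
#' @param minprop,maxprop allowed range for the proportion of patients
#'   at or below the cutpoint; defaults 0.1 and 0.9.
#' @param n_perm if > 0, additionally estimate a Monte-Carlo
#'   permutation p-value for the maximum with this many permutations.
#' @param perm_seed seed for the permutation draw.
#' @return A `maxstat_result` list: `cutpoint`, `statistic` (the
#'   standardized maximum b), `p_approx`, `p_permutation` (or `NA`),
#'   `direction` (+1 if the above-cutpoint side is high risk),
#'   `n_candidates`, `window` = c(q1, q2).
#' @export
maxstat_cutpoint <- function(x, times, events, minprop = 0.1, maxprop = 0.9,
                             n_perm = 0L, perm_seed = 1L) {
  check_surv_input(times, events)
  if (length(x) != length(times)) stop("'x' length must match 'times'", call. = FALSE)
  if (any(!is.finite(x))) stop("'x' must be finite", call. = FALSE)
  if (!(minprop < maxprop)) stop("'minprop' must be < 'maxprop'", call. = FALSE)
  scores <- logrank_scores(times, events)
  scan <- maxstat_scan(x, scores, minprop, maxprop)
  tstd <- scan_statistics(scan, scores)
  best <- which.max(abs(tstd))           # ties: which.max takes the first = smallest mu
  b <- abs(tstd[best])
  p_perm <- NA_real_
  if (n_perm > 0L) {
    set.seed(perm_seed)
    exceed <- vapply(seq_len(n_perm), function(i)
      max(abs(scan_statistics(scan, sample(scores)))) >= b, logical(1))
    p_perm <- (1 + sum(exceed)) / (n_perm + 1)
  }
  structure(list(cutpoint = scan$cuts[best], statistic = b,
                 p_approx = maxstat_pvalue(b, scan$q1, scan$q2),
                 p_permutation = p_perm,
                 direction = if (tstd[best] < 0) 1 else -1,
                 n_candidates = length(scan$cuts),
                 window = c(q1 = scan$q1, q2 = scan$q2)),
            class = "maxstat_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (step-up: sorted ascending,
#' `adj_(i) = min_{j>=i} (m/j) p_(j)` capped at 1, mapped back to the
#' input order). Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, elementwise >= the input and <= 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Two-cohort screening of prognostic genes
#'
#' Runs [maxstat_cutpoint()] for every probe in each cohort, adjusts
#' p-values by Benjamini-Hochberg within each cohort separately across
#' the tested probes, and selects probes whose adjusted p-value falls
#' below `alpha` in BOTH cohorts. The training cohort's cutpoints and
#' risk directions are the ones carried downstream.
#'
#' @param train,valid cohorts as returned by [align_cohort()] /
#'   [generate_cohort()]: lists with `expr` and `clin`.
#' @param probes probe ids to test; defaults to all probes of the
#'   training expression matrix. Probes absent from either cohort are
#'   excluded with a warning.
#' @param alpha per-cohort adjusted significance level (default 0.05).
#' @param minprop,maxprop cutpoint window, as in [maxstat_cutpoint()].
#' @return A `screening_result` data.frame: per probe the training and
#'   validation cutpoint, statistic, raw and adjusted p, direction, and
#'   a logical `selected`.
#' @export
screen_prognostic_genes <- function(train, valid, probes = NULL,
                                    alpha = 0.05, minprop = 0.1,
                                    maxprop = 1 - minprop) {
  if (is.null(probes)) probes <- rownames(train$expr)
  missing <- probes[!(probes %in% rownames(train$expr)) |
                      !(probes %in% rownames(valid$expr))]
  if (length(missing)) {
    warning("probe(s) absent from a cohort, excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
    probes <- setdiff(probes, missing)
  }
  if (!length(probes)) stop("no probes shared by both cohorts", call. = FALSE)

  scan_cohort <- function(cohort) {
    res <- lapply(probes, function(pr)
      maxstat_cutpoint(cohort$expr[pr, ], cohort$clin$os_months,
                       cohort$clin$os_event, minprop, maxprop))
    data.frame(cutpoint = vapply(res, `[[`, 0, "cutpoint"),
               statistic = vapply(res, `[[`, 0, "statistic"),
               p = vapply(res, `[[`, 0, "p_approx"),
               direction = vapply(res, `[[`, 0, "direction"))
  }
  tr <- scan_cohort(train)
  va <- scan_cohort(valid)
  out <- data.frame(
    probe = probes,
    cutpoint_train = tr$cutpoint, statistic_train = tr$statistic,
    p_train = tr$p, padj_train = bh_adjust(tr$p), direction_train = tr$direction,
    cutpoint_valid = va$cutpoint, statistic_valid = va$statistic,
    p_valid = va$p, padj_valid = bh_adjust(va$p), direction_valid = va$direction,
    stringsAsFactors = FALSE)
  out$selected <- out$padj_train < alpha & out$padj_valid < alpha
  class(out) <- c("screening_result", class(out))
  out
}
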