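# 1 when the patient sits on the high-risk side of a gene's cutoff;
# values exactly at the cutoff count as "below" (low side).
risk_indicator <- function(x, cutoff, direction) {
  above <- x > cutoff
  as.integer(if (direction >= 0) above else !above)
}

risk_matrix <- function(genes, expr) {
  missing <- setdiff(genes$probe_id, rownames(expr))
  if (length(missing))
    stop("probe(s) missing from cohort: ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- vapply(seq_len(nrow(genes)), function(i)
    risk_indicator(expr[genes$probe_id[i], ], genes$cutoff[i], genes$direction[i]),
    integer(ncol(expr)))
  s <- matrix(s, ncol = nrow(genes), dimnames = list(NULL, genes$probe_id))
  s
}

#' Prune screened genes by multivariate Cox regression
#'
#' Fits one multivariate Cox model on the dichotomized (risk-direction)
#' indicators of all screened genes in the training cohort and retains
#' those whose multivariate Wald p-value is below `alpha` — the genes
#' that remain independent prognostic factors. With a single screened
#' gene the multivariate fit reduces to the univariate one.
#'
#' @param screening a [screen_prognostic_genes()] result (its selected
#'   rows are used), or any data.frame with `probe`, `cutpoint_train`,
#'   `direction_train` columns.
#' @param cohort training cohort (`expr`, `clin`).
#' @param alpha Wald significance level for retention (default 0.05).
#' @return data.frame of retained genes: `probe_id`, `cutoff`,
#'   `direction`, `beta_multivariate`, `p_multivariate`.
#' @export
prune_multivariate <- function(screening, cohort, alpha = 0.05) {
  sel <- if ("selected" %in% names(screening)) screening[screening$selected, ]
         else screening
  if (nrow(sel) < 1L) stop("no selected genes to prune", call. = FALSE)
  genes <- data.frame(probe_id = sel$probe, cutoff = sel$cutpoint_train,
                      direction = sel$direction_train, stringsAsFactors = FALSE)
  s <- risk_matrix(genes, cohort$expr)
  fit <- cox_fit(s, cohort$clin$os_months, cohort$clin$os_event)
  if (!fit$converged)
    stop("multivariate Cox pruning fit did not converge", call. = FALSE)
  keep <- fit$coefficients$p_value < alpha
  data.frame(probe_id = genes$probe_id[keep],
             cutoff = genes$cutoff[keep],
             direction = genes$direction[keep],
             beta_multivariate = fit$coefficients$beta[keep],
             p_multivariate = fit$coefficients$p_value[keep],
             stringsAsFactors = FALSE)
}

# Merge empty raw count groups into the nearest non-empty neighbor,
# preferring the higher count, then iteratively merge the adjacent
# pair with the largest two-sample log-rank p until all adjacent pairs
# differ at merge_alpha. Returns the frozen count -> merged label map.
merge_count_groups <- function(high_count, times, events, k, merge_alpha) {
  occupied <- tabulate(high_count + 1L, nbins = k + 1L) > 0L
  grp <- cumsum(occupied)
  for (c in seq_len(k + 1L)) {
    if (!occupied[c]) {
      above <- which(occupied & seq_len(k + 1L) > c)
      below <- which(occupied & seq_len(k + 1L) < c)
      grp[c] <- if (length(above)) grp[min(above)] else grp[max(below)]
    }
  }
  repeat {
    g <- grp[high_count + 1L]
    levels <- sort(unique(g))
    if (length(levels) < 2L) break
    pvals <- vapply(seq_len(length(levels) - 1L), function(i) {
      in_pair <- g %in% levels[c(i, i + 1L)]
      logrank_test(times[in_pair], events[in_pair], g[in_pair])$p_value
    }, 0)
    if (max(pvals) < merge_alpha) break
    i <- which.max(pvals)
    grp[grp == levels[i + 1L]] <- levels[i]
  }
  # relabel contiguously from 1
  relab <- match(grp, sort(unique(grp)))
  setNames(as.integer(relab), as.character(0:k))
}

#' Build and freeze a risk-score model on a training cohort
#'
#' Each retained gene contributes `+beta` to a patient's score when the
#' patient sits on the gene's high-risk side of its frozen cutoff and
#' `-beta` otherwise; `beta` is by default the univariate Cox log
#' hazard ratio of the gene's dichotomy in the training cohort. Raw
#' risk groups are the counts of high-risk genes (0..K); adjacent
#' groups whose overall survival does not differ by a two-sample
#' log-rank test at `merge_alpha` are merged iteratively (largest p
#' first), and the resulting count-to-group map is frozen into the
#' model.
#'
#' @param genes data.frame with `probe_id`, `cutoff`, `direction` (and
#'   `beta_multivariate` when `beta_source = "multivariate"`), e.g.
#'   from [prune_multivariate()].
#' @param cohort training cohort (`expr`, `clin`).
#' @param merge_alpha log-rank level below which adjacent groups stay
#'   separate (default 0.05).
#' @param beta_source `"univariate"` (default) or `"multivariate"`.
#' @return list with `model` (an [episcore_model()]) and `assignment`
#'   (the training-cohort [apply_model()] assignment).
#' @export
build_model <- function(genes, cohort, merge_alpha = 0.05,
                        beta_source = c("univariate", "multivariate")) {
  beta_source <- match.arg(beta_source)
  if (nrow(genes) < 1L) stop("need at least one gene", call. = FALSE)
  s <- risk_matrix(genes, cohort$expr)
  times <- cohort$clin$os_months
  events <- cohort$clin$os_event

  beta <- if (beta_source == "multivariate") {
    if (is.null(genes$beta_multivariate))
      stop("beta_source = 'multivariate' needs a 'beta_multivariate' column",
           call. = FALSE)
    genes$beta_multivariate
  } else {
    vapply(seq_len(ncol(s)), function(j)
      cox_fit(s[, j, drop = FALSE], times, events)$coefficients$beta, 0)
  }

  k <- nrow(genes)
  high_count <- rowSums(s)
  if (length(unique(high_count)) < 2L) {
    warning("fewer than 2 non-empty raw groups; model has a single group",
            call. = FALSE)
    merge_map <- setNames(rep(1L, k + 1L), as.character(0:k))
  } else {
    merge_map <- merge_count_groups(high_count, times, events, k, merge_alpha)
  }
  model <- episcore_model(
    data.frame(probe_id = genes$probe_id, cutoff = genes$cutoff,
               beta = beta, direction = genes$direction,
               stringsAsFactors = FALSE),
    merge_map,
    metadata = list(beta_source = beta_source, merge_alpha = merge_alpha,
                    n_train = length(times)))
  list(model = model, assignment = apply_model(model, cohort)$assignment)
}

#' Apply a frozen risk-score model to a cohort
#'
#' Uses the stored cutoffs, betas, risk directions and group-merge map
#' with no re-estimation: each patient gets a continuous score
#' `sum_g beta_g * (+/-1)`, the count of high-risk genes, and the
#' merged risk-group label; the k-group log-rank test across merged
#' groups quantifies the stratification.
#'
#' @param model an [episcore_model()].
#' @param cohort list with `expr` and `clin`; all model probes must be
#'   present.
#' @return list with `assignment` (data.frame: `patient_id`, `score`,
#'   `high_count`, `group`) and `logrank` (a [logrank_test()] result,
#'   or `NULL` with a warning when all patients fall into one group).
#' @export
apply_model <- function(model, cohort) {
  stopifnot(inherits(model, "episcore_model"))
  s <- risk_matrix(model$genes, cohort$expr)
  score <- as.vector(s %*% model$genes$beta - (1 - s) %*% model$genes$beta)
  high_count <- rowSums(s)
  group <- unname(model$merge_map[as.character(high_count)])
  assignment <- data.frame(patient_id = cohort$clin$patient_id,
                           score = score, high_count = high_count,
                           group = group, stringsAsFactors = FALSE)
  lr <- if (length(unique(group)) < 2L) {
    warning("all patients fall in a single risk group; log-rank undefined",
            call. = FALSE)
    NULL
  } else {
    logrank_test(cohort$clin$os_months, cohort$clin$os_event, group)
  }
  list(assignment = assignment, logrank = lr)
}

#' Compare the risk score against competing prognostic covariates
#'
#' The merged risk group enters the Cox model as a single ordinal term
#' (0, 1, 2, ...). In `"pairwise"` mode one bivariate model is fitted
#' per competing covariate; in `"joint"` mode all covariates enter one
#' model together. Covariates constant after complete-case filtering
#' are excluded with a warning. Complete-case analysis per fitted
#' model.
#'
#' @param assignment an [apply_model()] assignment.
#' @param cohort list with `clin` holding the covariate columns.
#' @param covariates character vector of `clin` column names.
#' @param mode `"pairwise"` (default) or `"joint"`.
#' @return data.frame: `model` (covariate or "joint"), `term`, `beta`,
#'   `hazard_ratio`, `se`, `z`, `p_value`.
#' @export
compare_covariates <- function(assignment, cohort, covariates,
                               mode = c("pairwise", "joint")) {
  mode <- match.arg(mode)
  clin <- cohort$clin
  idx <- match(assignment$patient_id, clin$patient_id)
  if (anyNA(idx)) stop("assignment patients missing from clinical table", call. = FALSE)
  clin <- clin[idx, , drop = FALSE]
  episcore_ord <- assignment$group - min(assignment$group)

  absent <- setdiff(covariates, names(clin))
  if (length(absent))
    stop("covariate(s) missing from clinical table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  usable <- character(0)
  for (cv in covariates) {
    v <- clin[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("degenerate covariate excluded: ", cv, call. = FALSE)
    } else usable <- c(usable, cv)
  }

  fit_one <- function(xdf, label) {
    fit <- cox_fit(xdf, clin$os_months, clin$os_event)
    cbind(model = label, fit$coefficients, converged = fit$converged,
          stringsAsFactors = FALSE)
  }
  if (mode == "pairwise") {
    out <- lapply(usable, function(cv)
      fit_one(data.frame(episcore = episcore_ord, clin[cv]), cv))
    do.call(rbind, out)
  } else {
    fit_one(data.frame(episcore = episcore_ord, clin[usable]), "joint")
  }
}
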