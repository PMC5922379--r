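#' Describe a planted prognostic gene
#'
#' A planted gene acts on the hazard through a step function: patients
#' whose expression exceeds the (hidden) cutpoint carry an extra
#' log-hazard of `beta`. The cutpoint is expressed as a quantile of the
#' gene's marginal expression distribution and realized on the sampled
#' cohort.
#'
#' @param gene_index integer index of the gene (row of the expression
#'   matrix) carrying the effect.
#' @param beta log hazard ratio of the above-cutpoint group versus the
#'   below-cutpoint group (dimensionless).
#' @param cut_quantile hidden cutpoint as an expression quantile,
#'   strictly inside (0, 1).
#' @return A `planted_gene` list.
#' @export
planted_gene <- function(gene_index, beta, cut_quantile) {
  if (length(gene_index) != 1L || gene_index < 1 || gene_index != round(gene_index))
    stop("invalid cohort spec: 'gene_index' must be a positive integer", call. = FALSE)
  if (!is.finite(beta))
    stop("invalid cohort spec: 'beta' must be finite", call. = FALSE)
  if (!is.finite(cut_quantile) || cut_quantile <= 0 || cut_quantile >= 1)
    stop("invalid cohort spec: 'cut_quantile' must lie strictly in (0, 1)", call. = FALSE)
  structure(list(gene_index = as.integer(gene_index), beta = beta,
                 cut_quantile = cut_quantile),
            class = "planted_gene")
}

#' Specify a synthetic expression + survival cohort
#'
#' Defines the generative model used throughout the package's
#' validation: a genes-by-patients matrix of positive, microarray-like
#' signals (log-normal: normal on the log2 scale), an exponential
#' baseline hazard modulated by the planted genes' step functions, and
#' independent uniform censoring.
#'
#' Defaults emulate an R-CHOP-era lymphoma cohort: baseline hazard of
#' 0.01 events/month with a 120-month censoring horizon gives an
#' expected event fraction near 0.42 in the absence of planted effects.
#'
#' @param n_patients,n_genes positive integers.
#' @param planted_genes list of [planted_gene()] objects (may be empty).
#' @param baseline_rate exponential baseline hazard, events per month.
#' @param censor_horizon censoring times are Uniform(0, horizon) months.
#' @param expression_mean,expression_sd location and scale of gene
#'   expression on the log2 scale (recycled per gene).
#' @param seed integer; identical seed gives a bit-identical cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, n_genes, planted_genes = list(),
                        baseline_rate = 0.01, censor_horizon = 120,
                        expression_mean = 7, expression_sd = 1,
                        seed = 1L) {
  if (length(n_patients) != 1L || !is.finite(n_patients) || n_patients < 1 ||
      n_patients != round(n_patients))
    stop("invalid cohort spec: 'n_patients' must be a positive integer", call. = FALSE)
  if (length(n_genes) != 1L || !is.finite(n_genes) || n_genes < 1 ||
      n_genes != round(n_genes))
    stop("invalid cohort spec: 'n_genes' must be a positive integer", call. = FALSE)
  if (!is.finite(baseline_rate) || baseline_rate <= 0)
    stop("invalid cohort spec: 'baseline_rate' must be > 0", call. = FALSE)
  if (!is.finite(censor_horizon) || censor_horizon <= 0)
    stop("invalid cohort spec: 'censor_horizon' must be > 0", call. = FALSE)
  planted_genes <- lapply(planted_genes, function(g) {
    if (!inherits(g, "planted_gene"))
      g <- planted_gene(g$gene_index, g$beta, g$cut_quantile)
    g
  })
  if (length(planted_genes) > n_genes)
    stop("invalid cohort spec: more planted genes than genes", call. = FALSE)
  idx <- vapply(planted_genes, `[[`, integer(1), "gene_index")
  if (anyDuplicated(idx))
    stop("invalid cohort spec: duplicated planted gene index", call. = FALSE)
  if (any(idx > n_genes))
    stop("invalid cohort spec: planted gene index exceeds 'n_genes'", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 planted_genes = planted_genes,
                 baseline_rate = baseline_rate,
                 censor_horizon = censor_horizon,
                 expression_mean = rep_len(expression_mean, n_genes),
                 expression_sd = rep_len(expression_sd, n_genes),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic per-component RNG streams derived from the single
# global seed, so adding patients to one component cannot shift the
# draws of another.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic cohort with known prognostic structure
#'
#' Expression for gene g is 2^Normal(mean_g, sd_g). Patient j's hazard
#' is `baseline_rate * exp(sum_g beta_g * 1[x_gj > c_g])` where `c_g`
#' is the realized `cut_quantile` quantile of gene g's sampled
#' expression; the event time is exponential with that rate, censoring
#' is Uniform(0, `censor_horizon`) and independent, the observed time
#' is the minimum of the two and the event indicator is 1 iff the event
#' precedes censoring.
#'
#' @param spec a [cohort_spec()].
#' @return list with `expr` (an `expression_matrix`), `clin` (a
#'   clinical `data.frame` with `patient_id`, `os_months`, `os_event`)
#'   and `truth` (planted genes with the realized cutpoints appended).
#' @examples
#' cohort <- generate_cohort(cohort_spec(60, 10, seed = 7))
#' mean(cohort$clin$os_event)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec", call. = FALSE)
  seeds <- derive_seeds(spec$seed, 2L)
  n <- spec$n_patients
  p <- spec$n_genes

  set.seed(seeds[1L])
  values <- 2 ^ (matrix(rnorm(p * n), nrow = p) * spec$expression_sd +
                   spec$expression_mean)
  probe_ids <- sprintf("probe_%04d", seq_len(p))
  patient_ids <- sprintf("PT%04d", seq_len(n))
  expr <- expression_matrix(probe_ids, patient_ids, values)

  eta <- numeric(n)
  truth <- lapply(spec$planted_genes, function(g) {
    cut <- unname(quantile(values[g$gene_index, ], g$cut_quantile))
    eta <<- eta + g$beta * (values[g$gene_index, ] > cut)
    c(g, list(cutpoint = cut))
  })

  set.seed(seeds[2L])
  event_time <- rexp(n, rate = spec$baseline_rate * exp(eta))
  censor_time <- runif(n, 0, spec$censor_horizon)
  clin <- data.frame(patient_id = patient_ids,
                     os_months = pmin(event_time, censor_time),
                     os_event = as.integer(event_time <= censor_time),
                     stringsAsFactors = FALSE)
  list(expr = expr, clin = clin, truth = truth)
}

#' Sample a 2x2 contingency table with a prescribed log odds ratio
#'
#' Cell probabilities are solved so the row and column marginals match
#' the requested fractions and the log odds ratio equals `log_odds`;
#' counts are then one multinomial draw of size `n`. Used to exercise
#' exact association tests under a known effect.
#'
#' @param n total count (>= 4).
#' @param marginals length-2 numeric in (0,1): P(row 1) and P(col 1).
#' @param log_odds finite log odds ratio of the 2x2 probability table.
#' @param seed integer seed.
#' @return 2x2 integer matrix of counts summing to `n`.
#' @export
generate_contingency_cohort <- function(n, marginals, log_odds, seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 4)
    stop("invalid cohort spec: 'n' must be >= 4", call. = FALSE)
  if (length(marginals) != 2L || any(!is.finite(marginals)) ||
      any(marginals <= 0) || any(marginals >= 1))
    stop("invalid cohort spec: marginal fractions must lie in (0, 1)", call. = FALSE)
  if (length(log_odds) != 1L || !is.finite(log_odds))
    stop("invalid cohort spec: 'log_odds' must be finite", call. = FALSE)
  pr <- marginals[1L]; pc <- marginals[2L]
  psi <- exp(log_odds)
  if (psi == 1) {
    p11 <- pr * pc
  } else {
    # smaller root of the standard quadratic linking p11 to the odds ratio
    s <- 1 + (pr + pc) * (psi - 1)
    p11 <- (s - sqrt(s^2 - 4 * psi * (psi - 1) * pr * pc)) / (2 * (psi - 1))
  }
  probs <- c(p11, pr - p11, pc - p11, 1 - pr - pc + p11)
  if (any(probs < -1e-12)) stop("marginals incompatible with requested odds", call. = FALSE)
  probs <- pmax(probs, 0)
  set.seed(seed)
  counts <- rmultinom(1L, n, probs)
  matrix(as.integer(counts), nrow = 2L, byrow = TRUE,
         dimnames = list(row = c("r1", "r2"), col = c("c1", "c2")))
}

#' Generate a cohort with prescribed count-group survival laws
#'
#' Designed cohort for exercising the count-based risk grouping: K
#' indicator-like genes are arranged so that a patient in group c has
#' exactly c genes on the high side of a cutoff of 1 (high values near
#' 2, low near 0, with small noise so the marker is continuous), and
#' survival is exponential with the group's own hazard rate under
#' independent Uniform(0, horizon) censoring.
#'
#' @param n_per_group integer vector: patients in count groups 0..K
#'   (length K+1).
#' @param hazard_rates per-group exponential rates, same length.
#' @param censor_horizon censoring horizon in months.
#' @param seed integer seed.
#' @return list with `cohort` (`expr`, `clin`), `genes` (a data.frame
#'   of `probe_id`, `cutoff`, `direction` ready for [build_model()])
#'   and `group` (the true count per patient).
#' @export
generate_group_cohort <- function(n_per_group, hazard_rates,
                                  censor_horizon = 120, seed = 1L) {
  k <- length(n_per_group) - 1L
  if (k < 1L) stop("need at least 2 count groups", call. = FALSE)
  if (length(hazard_rates) != k + 1L)
    stop("'hazard_rates' must have one rate per count group", call. = FALSE)
  if (any(!is.finite(hazard_rates)) || any(hazard_rates <= 0))
    stop("hazard rates must be positive", call. = FALSE)
  n <- sum(n_per_group)
  group <- rep(0:k, n_per_group)
  seeds <- derive_seeds(seed, 2L)

  set.seed(seeds[1L])
  values <- vapply(seq_len(k), function(g)
    ifelse(group >= g, 2, 0) + runif(n, -0.2, 0.2), numeric(n))
  expr <- expression_matrix(sprintf("gene_%02d", seq_len(k)),
                            sprintf("PT%04d", seq_len(n)), t(values))

  set.seed(seeds[2L])
  event_time <- rexp(n, hazard_rates[group + 1L])
  censor_time <- runif(n, 0, censor_horizon)
  clin <- data.frame(patient_id = colnames(expr),
                     os_months = pmin(event_time, censor_time),
                     os_event = as.integer(event_time <= censor_time),
                     stringsAsFactors = FALSE)
  list(cohort = list(expr = expr, clin = clin),
       genes = data.frame(probe_id = rownames(expr), cutoff = 1,
                          direction = 1, stringsAsFactors = FALSE),
       group = group)
}
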