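#' Kaplan-Meier product-limit estimator
#'
#' Wraps [survival::survfit()] and reports the step curve together with
#' the median survival under the convention: smallest event time t with
#' S(t) <= 0.5, or `NA` ("not reached"). At tied times events precede
#' censorings.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return A `survival_curve` list: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `median`.
#' @export
kaplan_meier <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  surv <- fit$surv
  median <- {
    at <- fit$time[fit$n.event > 0 & surv <= 0.5 + 1e-12]
    if (length(at)) min(at) else NA_real_
  }
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = surv, median = median),
            class = "survival_curve")
}

#' k-sample log-rank test
#'
#' Hypergeometric-variance log-rank chi-square with k-1 degrees of
#' freedom, via [survival::survdiff()].
#'
#' @param times,events as in [kaplan_meier()].
#' @param groups group labels, at least two non-empty levels.
#' @return A `logrank_result` list: `chi_square`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != length(times))
    stop("'groups' length must match 'times'", call. = FALSE)
  if (nlevels(groups) < 2L)
    stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  chi <- unname(fit$chisq)
  structure(list(chi_square = chi, df = df,
                 p_value = pchisq(chi, df, lower.tail = FALSE),
                 n_groups = nlevels(groups)),
            class = "logrank_result")
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with Efron tie correction via
#' [survival::coxph()] (Newton iteration, up to 100 steps). Per-term
#' Wald statistics are reported; `hazard_ratio` is `exp(beta)` exactly.
#'
#' @param covariates numeric matrix or data.frame, one column per
#'   covariate; no column may be constant.
#' @param times,events as in [kaplan_meier()].
#' @return A `cox_fit` list: `coefficients` data.frame (`term`, `beta`,
#'   `hazard_ratio`, `se`, `z`, `p_value`), `loglik`, `converged`, `n`,
#'   `n_events`.
#' @export
cox_fit <- function(covariates, times, events) {
  check_surv_input(times, events)
  x <- as.matrix(as.data.frame(covariates))
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(times))
    stop("covariate rows must match 'times'", call. = FALSE)
  cc <- complete.cases(x)
  if (!all(cc)) {
    x <- x[cc, , drop = FALSE]; times <- times[cc]; events <- events[cc]
  }
  const <- apply(x, 2L, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "),
         call. = FALSE)
  if (sum(events) < ncol(x))
    stop("fewer events than covariates", call. = FALSE)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  if (any(!is.finite(beta))) converged <- FALSE
  z <- beta / se
  structure(list(
    coefficients = data.frame(term = colnames(x), beta = beta,
                              hazard_ratio = exp(beta), se = se, z = z,
                              p_value = 2 * pnorm(-abs(z)),
                              stringsAsFactors = FALSE),
    loglik = fit$loglik[length(fit$loglik)],
    converged = converged, n = fit$n, n_events = fit$nevent),
    class = "cox_fit")
}

check_surv_input <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events))
    stop("'times' and 'events' lengths differ", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop("'events' must be 0 or 1", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "time points; median survival:",
      if (is.na(x$median)) "not reached" else format(x$median), "\n")
  invisible(x)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g (%d groups)\n",
              x$chi_square, x$df, x$p_value, x$n_groups))
  invisible(x)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties),", x$n, "patients,",
      x$n_events, "events", if (!x$converged) "[NOT CONVERGED]", "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
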