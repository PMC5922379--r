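# Shared fixture builders: everything is generated in code at test time.

# Right-censored null survival data (no covariate effect).
null_surv <- function(n, rate = 0.01, horizon = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- rexp(n, rate)
  cc <- runif(n, 0, horizon)
  list(times = pmin(tt, cc), events = as.numeric(tt <= cc))
}

# Brute-force product-limit estimator: events precede censorings at ties.
km_oracle <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(events[times == ut[i]])
    if (d > 0) s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Direct observed/expected/variance tabulation of the two-sample
# log-rank statistic (hypergeometric variance at each event time).
logrank_oracle_2s <- function(times, events, grp) {
  ut <- sort(unique(times[events == 1]))
  U <- 0; V <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & grp == 1)
    d <- sum(events[times == t])
    d1 <- sum(events[times == t & grp == 1])
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Step-up FDR adjustment straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummin((m / rev(seq_len(m))) * rev(p[o])))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}

# Two-sided Fisher p by explicit hypergeometric enumeration
# (sum of probabilities of all margin-consistent tables at most as
# probable as the observed one).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
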