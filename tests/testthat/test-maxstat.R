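test_that("log-rank scores match hand Nelson-Aalen values and sum to zero", {
  expect_equal(logrank_scores(c(1, 2), c(1, 1)), c(0.5, -0.5))
  expect_equal(logrank_scores(c(5, 9, 13), c(0, 0, 0)), c(0, 0, 0))

  set.seed(1)
  times <- sort(rexp(25, 0.1)) + seq(0, 1e-4, length.out = 25)  # distinct
  a <- logrank_scores(times, rep(1, 25))
  expect_lt(abs(sum(a)), 1e-12)
})

test_that("selection-adjusted p-value clamps, decays and validates its window", {
  expect_equal(maxstat_pvalue(0.5, 0.1, 0.9), 1)
  expect_equal(maxstat_pvalue(1, 0.1, 0.9), 1)
  bs <- seq(1.5, 6, by = 0.5)
  ps <- vapply(bs, maxstat_pvalue, 0, q1 = 0.1, q2 = 0.9)
  expect_true(all(diff(ps) < 0))
  expect_lt(maxstat_pvalue(6, 0.1, 0.9), 1e-6)
  expect_error(maxstat_pvalue(2, 0.9, 0.1), "window")
  expect_error(maxstat_pvalue(2, 0, 0.9), "window")
  expect_error(maxstat_pvalue(-1, 0.1, 0.9), ">= 0")
})

test_that("a planted step at the median is recovered near the median", {
  set.seed(33)
  n <- 300
  x <- rnorm(n)
  cut <- median(x)
  tt <- rexp(n, 0.02 * exp(log(3) * (x > cut)))
  cc <- runif(n, 0, 120)
  res <- maxstat_cutpoint(x, pmin(tt, cc), as.numeric(tt <= cc))
  qpos <- mean(x <= res$cutpoint)
  expect_gt(qpos, 0.40)
  expect_lt(qpos, 0.60)
  expect_equal(res$direction, 1)        # above-cutpoint side is high risk
  expect_gt(res$statistic, 3)
})

test_that("statistic and cutpoint quantile are invariant to monotone transforms", {
  set.seed(34)
  s <- null_surv(80)
  x <- rnorm(80)
  r1 <- maxstat_cutpoint(x, s$times, s$events)
  r2 <- maxstat_cutpoint(exp(x), s$times, s$events)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(mean(x <= r1$cutpoint), mean(exp(x) <= r2$cutpoint))
  expect_equal(r1$p_approx, r2$p_approx, tolerance = 1e-12)
})

test_that("degenerate markers are rejected", {
  s <- null_surv(20, seed = 5)
  expect_error(maxstat_cutpoint(rep(1, 20), s$times, s$events), "equal")
  expect_error(maxstat_cutpoint(rep(c(1, 2), 10), s$times, s$events),
               "fewer than 2 candidate")
  expect_error(maxstat_cutpoint(rnorm(20), s$times, s$events,
                                minprop = 0.6, maxprop = 0.4), "minprop")
})

test_that("approximate p is conservative for a null marker", {
  set.seed(35)
  rej <- vapply(1:500, function(i) {
    s <- null_surv(100)
    maxstat_cutpoint(rnorm(100), s$times, s$events)$p_approx < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)
})

test_that("selection penalty: adjusted p at least the pointwise log-rank p", {
  set.seed(36)
  for (rep in 1:10) {
    s <- null_surv(60)
    x <- rnorm(60)
    res <- maxstat_cutpoint(x, s$times, s$events)
    pointwise <- logrank_test(s$times, s$events, x <= res$cutpoint)$p_value
    expect_gte(res$p_approx + 1e-12, pointwise)
  }
})

test_that("approximate p upper-bounds the finite-sample permutation p", {
  set.seed(37)
  s <- null_surv(120)
  x <- rnorm(120)
  res <- maxstat_cutpoint(x, s$times, s$events, n_perm = 2000, perm_seed = 2)
  mc_se <- sqrt(res$p_permutation * (1 - res$p_permutation) / 2000)
  expect_gte(res$p_approx, res$p_permutation - 2 * mc_se)
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(38)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("a gene prognostic in the training cohort only is not selected", {
  planted <- list(planted_gene(1, log(3), 0.5))
  tr <- generate_cohort(cohort_spec(250, 20, planted, seed = 61))
  va <- generate_cohort(cohort_spec(250, 20, seed = 62))       # no effect
  scr <- screen_prognostic_genes(tr, va)
  expect_false(scr$selected[scr$probe == "probe_0001"])
  expect_true(all(scr$padj_train >= scr$p_train - 1e-15))
  expect_true(all(scr$selected == (scr$padj_train < 0.05 & scr$padj_valid < 0.05)))
})

test_that("probes absent from one cohort are excluded with a warning", {
  tr <- generate_cohort(cohort_spec(120, 6, seed = 63))
  va <- generate_cohort(cohort_spec(120, 6, seed = 64))
  va$expr <- va$expr[-2, ]
  class(va$expr) <- c("expression_matrix", "matrix", "array")
  expect_warning(scr <- screen_prognostic_genes(tr, va), "probe_0002")
  expect_false("probe_0002" %in% scr$probe)
  expect_equal(nrow(scr), 5L)
})
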