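# Screening-shaped data.frame for genes with known cutoffs, bypassing
# the maxstat scan when the test plants the dichotomy itself.
as_screening <- function(probes, cutoffs, directions = 1) {
  data.frame(probe = probes, cutpoint_train = cutoffs,
             direction_train = rep_len(directions, length(probes)),
             stringsAsFactors = FALSE)
}

test_that("multivariate pruning drops a collinear copy but keeps independent genes", {
  set.seed(71)
  n <- 800
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- 0.95 * x1 + sqrt(1 - 0.95^2) * rnorm(n)   # noisy copy of x1, r ~ 0.95
  cuts <- c(median(x1), median(x2), median(x3))
  eta <- log(2.5) * (x1 > cuts[1]) + log(2.5) * (x2 > cuts[2])
  tt <- rexp(n, 0.01 * exp(eta)); cc <- runif(n, 0, 120)
  cohort <- list(
    expr = expression_matrix(c("g1", "g2", "g3"), sprintf("P%03d", 1:n),
                             rbind(x1, x2, x3)),
    clin = data.frame(patient_id = sprintf("P%03d", 1:n),
                      os_months = pmin(tt, cc),
                      os_event = as.integer(tt <= cc)))
  kept <- prune_multivariate(as_screening(c("g1", "g2", "g3"), cuts), cohort)
  expect_setequal(kept$probe_id, c("g1", "g2"))
})

test_that("single-gene pruning reduces to the univariate Wald test", {
  set.seed(72)
  gc <- generate_cohort(cohort_spec(300, 3, list(planted_gene(1, log(3), 0.5)),
                                    seed = 73))
  scr <- as_screening("probe_0001", gc$truth[[1]]$cutpoint)
  kept <- prune_multivariate(scr, gc)
  uni <- cox_fit(data.frame(h = as.numeric(gc$expr[1, ] > gc$truth[[1]]$cutpoint)),
                 gc$clin$os_months, gc$clin$os_event)
  expect_equal(kept$p_multivariate, uni$coefficients$p_value, tolerance = 1e-10)
  expect_equal(nrow(kept), 1L)
})

test_that("pruning retains nothing when all genes are null (spot check)", {
  set.seed(74)
  retained <- vapply(1:20, function(i) {
    gc <- generate_cohort(cohort_spec(200, 5, seed = 740 + i))
    cuts <- apply(gc$expr, 1, median)
    nrow(prune_multivariate(as_screening(rownames(gc$expr), cuts), gc))
  }, 0)
  expect_gte(mean(retained == 0), 0.7)  # ~ (1 - alpha)^5 under the null
})

test_that("adjacent groups drawn from one survival law are merged", {
  gc <- generate_group_cohort(c(150, 150, 150, 150),
                              c(0.004, 0.015, 0.06, 0.06), seed = 81)
  bm <- build_model(gc$genes, gc$cohort)
  expect_identical(unname(bm$model$merge_map), c(1L, 2L, 3L, 3L))
})

test_that("identical survival laws collapse to a single group", {
  gc <- generate_group_cohort(c(100, 100, 100, 100), rep(0.02, 4), seed = 82)
  expect_warning(bm <- build_model(gc$genes, gc$cohort), "single risk group")
  expect_identical(unname(bm$model$merge_map), rep(1L, 4L))
})

test_that("strongly separated groups stay apart with ordered KM medians", {
  gc <- generate_group_cohort(c(500, 500, 500, 500),
                              0.004 * 4^(0:3), seed = 83)
  bm <- build_model(gc$genes, gc$cohort)
  expect_identical(unname(bm$model$merge_map), 1:4)
  meds <- vapply(1:4, function(g) {
    sel <- bm$assignment$group == g
    m <- kaplan_meier(gc$cohort$clin$os_months[sel],
                      gc$cohort$clin$os_event[sel])$median
    if (is.na(m)) Inf else m            # "not reached" outlives every group
  }, 0)
  expect_true(all(diff(meds) < 0))      # higher risk group, shorter median
})

test_that("empty raw count groups fold into their higher neighbor before testing", {
  gc <- generate_group_cohort(c(150, 0, 150, 150),
                              c(0.004, 0.004, 0.06, 0.06), seed = 84)
  bm <- build_model(gc$genes, gc$cohort)
  mm <- unname(bm$model$merge_map)
  expect_equal(mm[2], mm[3])            # count 1 mapped with count 2
  expect_lt(mm[1], mm[3])               # low-risk group stays separate
})

test_that("scores are coherent with counts and merged labels preserve order", {
  gc <- generate_group_cohort(c(120, 120, 120, 120),
                              c(0.004, 0.012, 0.04, 0.1), seed = 85)
  bm <- build_model(gc$genes, gc$cohort)
  a <- bm$assignment
  expect_true(all(bm$model$genes$beta > 0))
  agg <- tapply(a$score, a$high_count, unique)
  expect_true(all(diff(unlist(agg)) > 0))          # score increasing in count
  expect_true(all(diff(a$group[order(a$score)]) >= 0))
})

test_that("applying a model to its training cohort reproduces the assignment", {
  gc <- generate_group_cohort(c(100, 100, 100, 100),
                              c(0.004, 0.015, 0.05, 0.12), seed = 86)
  bm <- build_model(gc$genes, gc$cohort)
  again <- apply_model(bm$model, gc$cohort)
  expect_identical(again$assignment, bm$assignment)
})

test_that("serialization round trip reproduces assignments bit-exactly", {
  gc <- generate_group_cohort(c(100, 100, 100, 100),
                              c(0.004, 0.015, 0.05, 0.12), seed = 87)
  bm <- build_model(gc$genes, gc$cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(bm$model, path)
  thawed <- read_model(path)
  expect_identical(apply_model(thawed, gc$cohort)$assignment, bm$assignment)
})

test_that("a frozen model generalizes to a cohort from the same law", {
  train <- generate_group_cohort(c(200, 200, 200, 200),
                                 c(0.004, 0.015, 0.05, 0.12), seed = 88)
  valid <- generate_group_cohort(c(75, 75, 75, 75),
                                 c(0.004, 0.015, 0.05, 0.12), seed = 89)
  bm <- build_model(train$genes, train$cohort)
  ap <- apply_model(bm$model, valid$cohort)
  expect_lt(ap$logrank$p_value, 0.01)
  grp_meds <- vapply(sort(unique(ap$assignment$group)), function(g) {
    sel <- ap$assignment$group == g
    km <- kaplan_meier(valid$cohort$clin$os_months[sel],
                       valid$cohort$clin$os_event[sel])
    if (is.na(km$median)) Inf else km$median
  }, 0)
  expect_true(all(diff(grp_meds) <= 0))
})

test_that("missing probes and single-group cohorts are flagged on application", {
  gc <- generate_group_cohort(c(100, 100, 100, 100),
                              c(0.004, 0.015, 0.05, 0.12), seed = 90)
  bm <- build_model(gc$genes, gc$cohort)
  short <- gc$cohort
  short$expr <- short$expr[-1, ]
  class(short$expr) <- c("expression_matrix", "matrix", "array")
  expect_error(apply_model(bm$model, short), "gene_01")

  low <- gc$cohort
  low$expr[] <- 0                                   # everyone below all cutoffs
  expect_warning(ap <- apply_model(bm$model, low), "single risk group")
  expect_true(all(ap$assignment$high_count == 0))
  expect_null(ap$logrank)
})

test_that("risk grouping stays prognostic next to a pure-noise covariate", {
  set.seed(91)
  gc <- generate_group_cohort(c(150, 150, 150, 150),
                              c(0.004, 0.015, 0.05, 0.12), seed = 92)
  gc$cohort$clin$noise <- rnorm(600)
  bm <- build_model(gc$genes, gc$cohort)
  uni <- cox_fit(data.frame(episcore = bm$assignment$group - 1),
                 gc$cohort$clin$os_months, gc$cohort$clin$os_event)
  cmp <- compare_covariates(bm$assignment, gc$cohort, "noise")
  p_epi_bi <- cmp$p_value[cmp$term == "episcore"]
  p_epi_uni <- uni$coefficients$p_value
  expect_gt(cmp$p_value[cmp$term == "noise"], 0.01)
  # log-scale agreement within a factor of 2 between bivariate and univariate p
  expect_lt(abs(log(p_epi_bi) - log(p_epi_uni)), log(100))
  expect_lt(p_epi_bi, 1e-6)
})

test_that("a covariate identical to the grouping is flagged as degenerate fit", {
  gc <- generate_group_cohort(c(150, 150, 150, 150),
                              c(0.004, 0.015, 0.05, 0.12), seed = 93)
  bm <- build_model(gc$genes, gc$cohort)
  gc$cohort$clin$twin <- bm$assignment$group - 1
  cmp <- compare_covariates(bm$assignment, gc$cohort, "twin", mode = "joint")
  expect_false(all(cmp$converged))
})

test_that("a fully mediating covariate absorbs the grouping's significance", {
  set.seed(94)
  n <- 600
  m <- rbinom(n, 1, 0.5)                      # the true driver of the hazard
  # genes are noisy readouts of the driver (some cross the cutoff wrongly),
  # so the risk grouping correlates with m without duplicating it
  x <- vapply(1:3, function(j) {
    flip <- as.numeric(runif(n) < 0.2)
    readout <- m * (1 - flip) + (1 - m) * flip
    readout * 2 + runif(n, -0.4, 0.4)
  }, numeric(n))
  tt <- rexp(n, 0.005 * exp(log(6) * m)); cc <- runif(n, 0, 120)
  cohort <- list(
    expr = expression_matrix(paste0("g", 1:3), sprintf("P%03d", 1:n), t(x)),
    clin = data.frame(patient_id = sprintf("P%03d", 1:n),
                      os_months = pmin(tt, cc),
                      os_event = as.integer(tt <= cc),
                      driver = m))
  genes <- data.frame(probe_id = paste0("g", 1:3), cutoff = 1, direction = 1)
  bm <- build_model(genes, cohort)
  cmp <- compare_covariates(bm$assignment, cohort, "driver")
  expect_gt(cmp$p_value[cmp$term == "episcore"], 0.05)
  expect_lt(cmp$p_value[cmp$term == "driver"], 0.05)
})

test_that("degenerate covariates are excluded with a warning", {
  gc <- generate_group_cohort(c(100, 100, 100, 100),
                              c(0.004, 0.015, 0.05, 0.12), seed = 95)
  gc$cohort$clin$flat <- 1
  gc$cohort$clin$ok <- rnorm(400)
  bm <- build_model(gc$genes, gc$cohort)
  expect_warning(cmp <- compare_covariates(bm$assignment, gc$cohort,
                                           c("flat", "ok")),
                 "degenerate covariate")
  expect_false("flat" %in% cmp$model)
  expect_true("ok" %in% cmp$model)
})
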