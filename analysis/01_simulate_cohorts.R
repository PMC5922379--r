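#!/usr/bin/env Rscript
# Simulate the study cohorts: a training and a validation cohort of 400
# patients x 100 genes, three of which act on survival through a step
# function at their median expression with log hazard ratio log(2.5).
# Writes the expression matrices (TSV), clinical tables (CSV) and the
# ground truth (JSON) under results/data/.

suppressPackageStartupMessages(library(episcore))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

beta_true <- log(2.5)
planted <- lapply(c(5, 20, 60), planted_gene, beta = beta_true,
                  cut_quantile = 0.5)

cohorts <- list(train = generate_cohort(cohort_spec(400, 100, planted, seed = 4001)),
                valid = generate_cohort(cohort_spec(400, 100, planted, seed = 4002)))

for (nm in names(cohorts)) {
  co <- cohorts[[nm]]
  write_expression(co$expr, file.path(out_dir, paste0(nm, "_expr.tsv")))
  write_clinical(co$clin, file.path(out_dir, paste0(nm, "_clin.csv")))
  cat(sprintf("%s cohort: %d patients, %d genes, %.0f%% events\n",
              nm, ncol(co$expr), nrow(co$expr), 100 * mean(co$clin$os_event)))
}

jsonlite::write_json(
  lapply(cohorts$train$truth, function(g)
    list(probe = sprintf("probe_%04d", g$gene_index), beta = g$beta,
         cut_quantile = g$cut_quantile, cutpoint = g$cutpoint)),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = 17)
cat("Planted genes:", sprintf("probe_%04d", c(5, 20, 60)),
    "| beta =", round(beta_true, 4), "at the median cutpoint\n")
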