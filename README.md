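# episcore

Builds and validates dichotomized gene-expression risk scores for
right-censored survival endpoints, the way prognostic scores are
constructed in lymphoma expression studies: screen candidate genes for an
optimal survival cutpoint, require replication in a second cohort, prune to
the genes that stay independent in a multivariate Cox model, combine them
into a ±β-weighted score with count-based risk groups, and apply the
frozen model to held-out cohorts. A synthetic-cohort generator with planted
step-function hazard effects gives every stage a known ground truth.

Intended users: biostatisticians and computational biologists building or
auditing expression-based survival stratifiers.

## The method

For a continuous marker *x* and right-censored follow-up, each candidate
cutpoint μ defines a two-group log-rank comparison through the rank scores
*aᵢ = δᵢ − Λ̂(tᵢ)* (Nelson–Aalen cumulative hazard). The maximally selected
rank statistic is

  b = max over μ of | T(μ) − E T(μ) | / sd T(μ),  T(μ) = Σ_{xᵢ ≤ μ} aᵢ,

scanned over cutpoints whose low-side proportion lies in [minprop,
maxprop]. The selection-adjusted p-value uses an improved-Bonferroni
(Miller–Siegmund-type) approximation for the supremum of a standardized
Brownian bridge over the scanned quantile window; a Monte-Carlo permutation
p-value is available as an alternative.

Screening runs this scan per probe in a training and a validation cohort,
adjusts p-values by Benjamini–Hochberg within each cohort, and keeps probes
with adjusted p < α in **both**. A multivariate Cox fit on the dichotomized
survivors prunes to independent prognostic genes. Each retained gene then
contributes +β (high-risk side) or −β to the patient score; risk groups are
counts of high-risk genes, merged by sequential two-sample log-rank tests
(adjacent pair with the largest p ≥ merge_alpha merges first, repeat).
The frozen model — cutoffs, βs, directions, group map — is applied to new
cohorts without re-estimation.

The package also provides the clinicopathological operations used around
such scores: two-sided Fisher exact tests (sum-of-small-probabilities
rule), pooled/Welch t-tests, exact paired signed-rank tests, and optimal
cutpoints for percent-positive immunohistochemistry markers.

## Worked example

The `analysis/` scripts run the full construction on synthetic cohorts
(400 patients × 100 genes per cohort, three genes planted with hazard
step β = log 2.5 at their median expression):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_screen_genes.R
Rscript analysis/03_build_score.R
Rscript analysis/04_validate_model.R
Rscript analysis/05_clinpath_tests.R
```

Screening recovers exactly the planted probes:

```
Screened 100 probes; 3 selected in both cohorts: probe_0005, probe_0020, probe_0060
Planted genes recovered: 3 of 3
```

Model building freezes their cutoffs and univariate Cox weights, and the
four count groups (0–3 high-risk genes) separate cleanly on this run — no
merging, ordered medians:

```
Training group sizes: group 1: 54 (13.5%), group 2: 145 (36.2%), group 3: 136 (34.0%), group 4: 65 (16.2%)
  group 1 median OS: 72.8 months
  group 2 median OS: 23.5 months
  group 3 median OS: 11.0 months
  group 4 median OS: 4.4 months
```

Applying the frozen model to the held-out cohort reproduces the
stratification (log-rank χ² = 154.8 on 3 df, p = 2.4e-33), and in pairwise
Cox comparisons the ordinal risk group stays significant (HR ≈ 2.47 per
group, p ≈ 1e-28) next to competing covariates. The association script
prints the exact-test p-values for the published 31-patient contingency
tables (0.0261, 0.2645, 0.7241).

`results/model.json` holds the frozen model; group assignments and the
screening table are written as CSV next to it. `analysis/01` regenerates
the cohort files under `results/data/`.

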