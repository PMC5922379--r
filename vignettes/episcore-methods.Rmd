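---
title: "Building dichotomized expression risk scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building dichotomized expression risk scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcore)
```

## The problem

In diffuse large B-cell lymphoma and similar settings, a handful of genes
whose expression stratifies overall survival can be combined into a simple
risk score that is portable across cohorts: each gene is dichotomized at an
optimal expression cutoff, and a patient's score is the sum of Cox
log-hazard-ratio weights, signed by which side of each cutoff the patient
falls on. This package implements that construction end to end — cutpoint
screening, FDR control across two cohorts, multivariate pruning, score and
risk-group formation, and frozen-model validation — together with a
synthetic-cohort generator that provides ground truth for every stage.

## The maximally selected rank statistic

For a continuous marker $x$ and right-censored follow-up, every candidate
cutpoint $\mu$ defines a two-group comparison. The package uses log-rank
scores

$$a_i = \delta_i - \hat\Lambda(t_i),$$

where $\delta_i$ is the event indicator and $\hat\Lambda$ the Nelson–Aalen
cumulative hazard evaluated at the patient's own time (events at $t_i$
included). The linear statistic at $\mu$ is
$T(\mu) = \sum_{x_i \le \mu} a_i$, standardized by its permutation mean
$m\bar a$ and variance $\frac{m(N-m)}{N(N-1)} \sum_i (a_i - \bar a)^2$,
with $m = \#\{x_i \le \mu\}$. The selected cutpoint maximizes
$|T_{\text{std}}(\mu)|$ over candidates (midpoints between consecutive
distinct marker values) whose low-side proportion lies in
$[\text{minprop}, \text{maxprop}]$; the maximum $b$ is the reported
statistic. Because only ranks of $x$ matter, both $b$ and the cutpoint's
quantile position are invariant under strictly monotone transforms — so the
screening stage is indifferent to whether expression is log-transformed,
while the downstream Cox weights are not.

Selecting the best cutpoint inflates the naive log-rank p-value. The
package adjusts with an improved-Bonferroni approximation of the
Miller–Siegmund type for the supremum of the standardized Brownian bridge
over the scanned quantile window $(q_1, q_2)$:

$$p \approx \frac{4\varphi(b)}{b} +
  \varphi(b)\Big(b - \frac{1}{b}\Big)
  \log\frac{q_2 (1-q_1)}{q_1 (1-q_2)},$$

clamped to 1 for $b \le 1$. Two properties matter in practice and are both
asserted by the test suite: the adjusted p-value is never smaller than the
pointwise log-rank p at the chosen cutpoint, and it upper-bounds the
finite-sample permutation p-value — at moderate $n$ the discrete candidate
maximum sits below the continuous supremum, so the approximation is
conservative; the gap closes as $n$ grows (the permutation cross-check in
the acceptance suite runs at $n = 2000$, where approximation and a
10,000-permutation Monte-Carlo estimate agree within Monte-Carlo error).
A Monte-Carlo permutation p-value is available directly from
`maxstat_cutpoint(..., n_perm = )` when the approximation's conservatism at
small $n$ is a concern, as with the 31-patient immunohistochemistry cohort
size served by `ihc_cutpoint()`.

## Two-cohort screening and pruning

`screen_prognostic_genes()` runs the scan per probe in a training and a
validation cohort, applies Benjamini–Hochberg correction *within each
cohort separately* across the tested probes, and selects probes with
adjusted $p < \alpha$ in **both** cohorts. Requiring both cohorts is a
replication filter: a probe prognostic in only one cohort is discarded no
matter how small its p-value. The training cohort's cutpoints and risk
directions are the ones frozen downstream. A selected gene whose
above-cutoff group has a hazard ratio below 1 has its direction flipped so
that "high" always denotes the worse-prognosis side; this keeps the
count-based grouping monotone in risk.

`prune_multivariate()` then fits one multivariate Cox model on all selected
dichotomized indicators and keeps genes with multivariate Wald $p < \alpha$
— the genes that remain *independent* prognostic factors. Note a
non-collapsibility subtlety: when several genes truly act on the hazard,
the univariate (marginal) log hazard ratio of one dichotomy is attenuated
relative to its conditional effect, so parameter-recovery checks compare
the multivariate estimates against the planted values.

## Score, risk groups, and the merging rule

For retained genes $g = 1..K$ with weights $\beta_g$, a patient's score is
$\sum_g \pm \beta_g$, positive when the patient is on gene $g$'s high-risk
side. By default $\beta_g$ is the *univariate* Cox coefficient of the
dichotomy in the training cohort (`beta_source = "multivariate"` is
available); the choice affects only the continuous score, because group
assignment uses the count of high-risk genes, 0..K.

Raw count groups are merged by sequential log-rank testing: among adjacent
group pairs, the pair with the largest two-sample log-rank p-value is
merged whenever that p-value is $\ge$ `merge_alpha` (default 0.05), and
the procedure repeats on the merged grouping until all adjacent pairs
differ. Empty count groups are first folded into their nearest non-empty
neighbor, preferring the higher count. The resulting count-to-group map is
frozen into the model; `apply_model()` performs no re-estimation of any
kind. Two behavioural notes:

* merging is a *null-acceptance* rule at level `merge_alpha` without
  multiplicity correction, so when adjacent groups truly share one
  survival law the collapse is the typical outcome but not a guaranteed
  one — a spurious boundary survives with probability governed by the
  test level;
* merging can only reduce the number of groups and always preserves the
  risk ordering (labels are a non-decreasing function of the count, hence
  of the score when all $\beta_g > 0$).

## The synthetic-cohort generator

`generate_cohort()` emulates the data the pipeline consumes, not the
platform that produced it. Expression is log-normal — Normal(7, 1) on the
log2 scale, i.e. positive microarray-like signals — and each planted gene
acts on the hazard through a step function at a hidden quantile cutpoint:

$$\lambda_j = \lambda_0 \exp\Big(\sum_g \beta_g\,
  \mathbf{1}[x_{gj} > c_g]\Big),$$

with exponential event times and independent Uniform(0, horizon)
censoring. Defaults are fixed as the package's study conditions:
$\lambda_0 = 0.01$ events/month and a 120-month horizon, giving a
closed-form expected event fraction
$1 - (1 - e^{-\lambda_0 H})/(\lambda_0 H) \approx 0.42$ — the rough death
fraction of an immunochemotherapy-era lymphoma cohort over ten years of
accrual. The generator does *not* emulate probe-level artifacts, batch
effects, gene–gene correlation blocks, or molecular-subgroup structure;
passing recovery tests therefore demonstrates the statistical machinery,
not robustness to those real-data features. `generate_group_cohort()` is a
designed variant that places patients at exact high-gene counts with
per-group survival laws, used to exercise the merging rule in isolation,
and `generate_contingency_cohort()` draws 2×2 tables at a prescribed log
odds ratio for the exact-test operations.

## Numerical conventions

* **Ties at a cutoff**: a marker value exactly equal to the stored cutoff
  scores as "below" (low side) everywhere — scan, score, and application.
* **Cutpoint ties**: among candidates with equal $|T_{\text{std}}|$, the
  smallest cutpoint wins.
* **Survival ties**: Efron's correction in all Cox fits; in Kaplan–Meier
  curves events precede censorings at tied times.
* **Median survival**: smallest observed event time with
  $S(t) \le 0.5$, otherwise "not reached".
* **Window**: `minprop = 0.1`, `maxprop = 0.9` by default — the
  conventional scan window for this statistic, exposed everywhere.
* **Fisher two-sided p**: sum-of-small-probabilities rule (all tables with
  the observed margins whose probability is at most the observed table's,
  with a $1 + 10^{-7}$ relative tolerance for float ties).
* **Signed-rank test**: for up to 25 non-zero pairs the sign-flip null
  distribution of the positive-rank sum is enumerated exactly by
  generating-function convolution on doubled midranks (well-defined under
  tied absolute differences); larger samples use the normal approximation
  with continuity correction. Zero differences are dropped first.
* **Serialization**: model JSON is written with 17 significant digits so a
  freeze/thaw cycle reproduces assignments bit-exactly.

## Validation problem sizes

The test and acceptance analyses run at sizes chosen to make each check
informative at interactive cost: recovery of three planted genes
($\beta = \log 2.5$ at the median) uses two cohorts of 400 patients × 100
genes; merging behaviour uses 4 × 150 patients per count group (2000 for
the no-merge scenario, so all four Kaplan–Meier medians are reached);
log-rank type-I error uses 1000 replicates of 200 patients; the
permutation cross-check of the selection-adjusted p-value uses $n = 2000$
with 10,000 permutations.

## Limitations

* The score handles a single right-censored endpoint; no time-varying
  covariates, stratification, or competing risks.
* The p-value approximation is asymptotic; at a few dozen patients prefer
  the permutation option.
* Probe-to-gene collapsing is out of scope: the pipeline operates on probe
  ids and leaves the choice among multiple probes per gene to the user.
* The merging rule is the minimal deterministic completion of "merge
  consecutive groups that do not differ"; alternatives (trend tests,
  multiplicity-corrected levels) would freeze different group maps.
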