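---
title: "Methods: linking self-report mental health to imaging-derived phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking self-report mental health to imaging-derived phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolink)
```

phenolink implements a complete analysis workflow for population imaging
studies that relate self-report mental-health questionnaires to brain
imaging-derived phenotypes (IDPs): scalar summaries of processed brain
images such as regional volumes, resting-state network amplitudes, or
network-edge correlations. This vignette explains the statistical
machinery, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The measures

Five summary measures are computed from ordinal questionnaire items, each
identified by its UK-Biobank-style data-field ID in the table's sidecar
column map:

* **RDS-4** (Recent Depressive Symptoms, fields 2050/2060/2070/2080): four
  scan-day items on depressed mood, disinterest, restlessness and
  tiredness over the past two weeks, coded 1–4, summed to 4–16. Because it
  is collected on the day of scanning it is the state-depression measure
  of choice for imaging analyses.
* **PHQ-9** (nine items, 0–3 each, sum 0–27) and **GAD-7** (seven items,
  0–3, sum 0–21), from an online questionnaire completed at a date that
  can be years away from the scan.
* **N-12** (twelve binary neuroticism items, sum 0–12), a trait measure
  collected on scan day.
* **Probable depression status**: 1 iff (ever depressed OR ever
  disinterested) AND (an episode lasting at least one week) AND (saw a GP
  OR a psychiatrist), from fields 4598/4631/4609/5375/2090/2100.

Missing or out-of-range items always propagate to a missing score; nothing
is imputed at the scoring stage, because the cohort filter later removes
subjects with incomplete mental-health data and silent imputation would
mask that rule. Internal consistency uses Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_j \sigma^2_j / \sigma^2_{\text{sum}}\bigr)$
with $n-1$ sample variances.

## Cohort construction

The subject flow applies, in order: (1) exclusion for mean resting head
motion strictly greater than 0.2 mm; (2) exclusion for any missing
mental-health summary; (3) set-aside of subjects with a second imaging
timepoint as the test–retest sample; (4) exclusion for probable late-onset
depression (first episode at age 60 or older), which has distinct brain
correlates; (5) greedy 1:1 matching of "ever seen GP for nerves, anxiety,
tension or depression" cases to never-seen controls; (6) a pair-level
random split, two thirds exploratory and one third confirmatory.

Matching processes cases in seeded random order, requires identical sex
and identical integer age (a tolerance is exposed but defaults to exact
matching, since ages are recorded in integer years), and takes the
candidate minimising the absolute head-motion difference, ties broken by
smallest subject ID for determinism. Pair-level splitting guarantees that
no subject appears in both samples and that each sample inherits the
matched sex ratio and mean age.

## Deconfounding, imputation, dimensionality reduction

All continuous analyses operate on residuals after regressing out the
standard imaging confound set: scanning site (one-hot, reference level
dropped), age, age², sex, age×sex, head size, head motion in resting and
task fMRI, acquisition date (days since the sample's earliest scan) and
date². Continuous columns are centered before squaring or interacting so
the quadratic and interaction terms stay well-conditioned; a
rank-deficient design is an error that names the collinear columns.
Confound models are refit within each sample (exploratory, confirmatory,
retest) — unlike the PCA and CCA weights, confound weights are never
transferred, since deconfounding is a per-sample normalization rather than
part of the learned model.

Missing IDP cells (structural and task modalities only) are skipped during
the nuisance regression and then filled by nearest-neighbour imputation:
the distance between two subjects is the Euclidean distance over the
variables observed in both rows within the same modality group, and a
missing cell receives the mean of its variable over the k nearest donors
(k = 1 by default, matching the common single-neighbour default of
standard implementations).

IDPs are then standardized and reduced by PCA separately for resting,
structural and task groups, keeping the minimal number of leading
components that explains at least 50% of variance per group. Separate
reduction prevents the numerically dominant resting block from crowding
out the much smaller structural and task blocks. Component signs follow a
deterministic convention (largest-magnitude loading positive). Held-out
samples are projected with the stored means, scalings and loadings — the
PCA is never refit — and models serialize to JSON at full precision so a
projection is reproducible across runs.

## CCA, permutation inference, and replication

With brain components $X$ and residualized mental-health scores $Y$, CCA
finds coefficients $A, B$ maximising successive correlations of
$U = XA$ and $V = YB$. The solver whitens each block by the inverse square
root of its covariance and takes the SVD of the whitened cross-covariance;
this keeps within-block orthogonality of canonical scores exact and is
numerically stable. The Y-side sign convention (largest |coefficient|
positive per mode) makes fits deterministic.

Because the leading canonical correlation is an explicitly maximized
statistic, its null distribution does not center on zero — with $p + q$
input variables and $n$ subjects the null leading correlation is of order
$(\sqrt{p} + \sqrt{q})/\sqrt{n}$. Significance therefore uses permutation
inference: the subject order of both blocks is shuffled independently
(both-block shuffling is redundant but implemented literally for fidelity
to the procedure it mirrors), the CCA is refit per permutation, and
$p_k = (1 + \#\{r^{perm}_k \ge r_k\})/(1 + n_{perm})$ with 2000
permutations by default, so p is never exactly zero.

Per-IDP contributions use the **averaged-UV loading**: $U_1$ and $V_1$ are
z-scored and averaged within subject, and this summary score is correlated
with every original (residualized) IDP. Correlating $U$ directly would be
optimistic, since $U$ is optimized for the brain block; the averaged score
is a more conservative estimate, and the package's tests verify the
optimism reduction. The two scores are z-scored before averaging — the
procedure this mirrors does not state a scaling, but without it the block
with larger score variance would dominate the average; this is documented
as a deliberate choice. Significance is Bonferroni-corrected across all
IDPs tested (with the full UKB-scale inventory of 3,466 + 346 + 16 IDPs
the threshold is 0.05/3828 = 1.3e-5).

Replication multiplies held-out projections by the training $A$ and $B$
and reports $r'_k = \mathrm{cor}(U'_k, V'_k)$. A held-out correlation is
not maximized, so its p value is the parametric correlation test,
Bonferroni-corrected by the number of modes (five here). Under the null
the held-out $r'$ is centred on zero — this contrast with the inflated
training statistic is the reason for the exploratory/confirmatory design.
Post-hoc interpretation of a second mode is skipped when its held-out
correlation is weak.

## Effect sizes and reliability

Univariate effect sizes of Bonferroni-selected IDPs are computed in the
confirmatory sample only: Cohen's d (pooled SD, $n-1$ weights) against raw
probable depression status — the one variable exempt from deconfounding,
because residualizing a binary label destroys its categorical nature — and
Pearson's r against each residualized continuous measure, grouped by
modality with box-summary statistics (quartiles, mean, median, 1.5 IQR
fences).

Test–retest reliability uses ICC(A,1), the two-way absolute-agreement
single-measure intraclass correlation
$\frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$ with
$k = 2$ sessions, which penalizes systematic between-session offsets.
Retest IDPs are deconfounded per timepoint with the same design as the
CCA analysis. Adjustment variants regress the inter-scan interval (or the
RDS-4 change) out of each timepoint's values before the ICC — the
procedure is ambiguous about which timepoint carries the adjustment, so
both-timepoint adjustment is the default with `"first"`/`"second"`
switches. Subgroup ICCs partition subjects by $|\Delta\text{RDS-4}| = 0$
versus $\ge 1$.

## Psychometric comparisons

Spearman rank correlations (average ranks for ties, two-sided p via the t
approximation) compare all measure pairs; two-sample Kolmogorov–Smirnov
tests (sup-distance, asymptotic p from the machine-converged Kolmogorov
series) compare score distributions by depression status. Equipercentile
linking maps scores between scales through mid-percentile ranks
$100\,(P(X < s) + \tfrac12 P(X = s))$, inverted on the target scale by
linear interpolation and clamped to the attained range; no presmoothing is
applied by default because the linking samples here are large. The
latency analysis bins subjects by the absolute number of days between
scan-day and online measurements (bins below 20 subjects are suppressed)
and reports the rank correlation per bin.

## What the generator emulates — and what it does not

`simulate_cohort()` is a first-class, tested model of the statistical
structure the pipeline assumes:

* A standard-normal **state-affect latent** $z$ drives scan-day depression
  items; a correlated (r = 0.6) **trait latent** $w$ with higher two-year
  stability (0.98 vs 0.89) drives the neuroticism items, so the 2-year
  self-correlations of the two scale families differ the way trait and
  state measures should (roughly 0.55 vs 0.8 at the default loadings).
  Online items are driven by $z$ propagated to the questionnaire date with
  autocorrelation $e^{-|\text{latency}|/1830\text{ days}}$, which makes
  the scan-day/online correlation decay with latency.
* Items follow a **graded threshold model**: equally spaced quantile
  cut-points on the standard-normal item propensity, shifted right by a
  per-scale constant so the score distributions show the right-skew
  characteristic of population samples.
* The IDP block carries a **planted rank-1 mode**: a carrier
  $t = c\,v + \sqrt{1 - c^2}\,u$ where $v$ is the standardized mean of the
  five standardized summary scores. Because $v$ lies in the span of the
  score block, the population canonical correlation between the blocks is
  exactly $c \cdot R_x$, where $R_x^2 = a^\top \Sigma_x^{-1} a$ is the
  best attainable IDP-side correlation with $t$ computed from the
  generator's own covariance ($a$ = per-IDP mode loadings, one shared
  latent factor per modality as structured noise, heteroscedastic
  residuals). The generator solves $c = \texttt{effect\_r} / R_x$ and
  rejects configurations that cannot be realized.
* **Reliability**: the carrier and factors are stable subject traits; the
  remaining noise is blended across timepoints with a per-modality
  coefficient chosen so the total test–retest correlation equals the
  configured per-modality reliability (structural 0.85, functional 0.45
  by default, reproducing the structural > functional ordering).
* **Confounds** enter the IDPs with fixed random coefficients scaled to
  about 5% of IDP variance, close to the share the standard confound set
  explains in real imaging data; site is a 3-level categorical (multiple
  scanning sites exist; the count is a modelling choice).
* **Missingness** is MCAR, confined to structural/task cells, at
  timepoint-independent positions — the weakest mechanism compatible with
  nearest-neighbour imputation.

Default sizes are a desk-scale stand-in for the real study: 126 IDPs
(resting 70, structural 52, task 4, mirroring the real inventory's
resting ≫ structural ≫ task ordering at about 1/30 scale) and cohorts of a
few thousand subjects rather than tens of thousands. IDP marginals are
Gaussian — their real-world distributions are unstated, and normality is
the neutral assumption.

What passing tests on this generator show is that the *pipeline machinery*
is correct: scores compute exactly, matching balances arms, planted
canonical structure is recovered and replicates, permutation inference is
calibrated, planted reliabilities are recovered. What they cannot show is
anything about real brains: real IDP blocks have heavier tails,
non-MCAR missingness, richer correlation structure than one factor per
modality, and true brain–behaviour modes that are neither rank-1 nor
linear. Published effect sizes from restricted cohorts are therefore not
reproduced numerically, by design.

## Numerical choices and problem sizes

* Whitening tolerates condition numbers up to 1e10 before declaring a
  block rank-deficient; degenerate inputs (constant scores, zero-variance
  IDPs) raise errors rather than propagating NaN.
* Ties in matching break by smallest subject ID; PCA and CCA signs follow
  largest-loading/largest-coefficient conventions; all randomized steps
  (generator, matching order, split, permutations) consume explicit seeds
  and a fixed seed reproduces outputs bit-identically.
* The test suite validates Monte-Carlo properties at sizes where sampling
  error is small relative to the tolerance being checked: canonical-mode
  recovery over 20 seeds at 2000 + 1000 subjects; permutation calibration
  with 200 repeats of 500 subjects x 500 permutations; reliability
  recovery with 2400 retest subjects so that a per-modality median over as
  few as four IDPs resolves a ±0.05 band. These sizes are package design
  choices balancing statistical resolution against runtime.

## Known limitations

Greedy matching is not optimal matching — it can strand matchable cases
when an early case consumes a control another case needed; the seeded
random order makes this unbiased on average. Exact integer-age matching is
stricter than caliper matching and drops more cases. The equipercentile
link uses no presmoothing, so mapped curves inherit sampling noise at rare
scores. The permutation scheme shuffles whole rows and thus assumes
exchangeable subjects (no family structure). ICC adjustment regresses
covariates per timepoint, not on differences, which is one of several
defensible readings of the procedure it mirrors.

## A worked run

```{r example, eval = FALSE}
res <- run_pipeline(sim_config(n_subjects = 3000, seed = 1),
                    n_perm = 2000)
print(res)
tidy(res$cca)
reliability_summary(res$reliability)
autoplot(res$cca)
plot_reliability(res$reliability)
```
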