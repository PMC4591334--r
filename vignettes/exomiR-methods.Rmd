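---
title: "Methods: screening, co-expression and classifier construction in exomiR"
author: "exomiR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, co-expression and classifier construction in exomiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomiR)
```

# Scope and data model

`exomiR` implements a complete case/control biomarker analysis for
small-RNA sequencing of plasma exosome preparations. The unit of
measurement is the *sequence variant* (isomiR): each distinct read sequence
aligned to a mature miRNA reference locus, counted per sample. The central
container, `MirCountSet`, extends `SummarizedExperiment`; `rowData` holds
the sequence-to-locus assignment, `colData` the sample metadata (diagnostic
group, sex, age, RNA-preparation batch, and the per-sample count of
genome-mappable reads).

The analysis chain is:

1. **Filter** sequences with fewer than 500 raw counts summed across all
   samples (`filterMinTotal`). The threshold is inclusive ("at least 500")
   and is defined on raw counts, before any normalization, because it is a
   sequencing-depth criterion, not an expression criterion.
2. **Normalize** to counts per million genome-mappable reads
   (`normalizeCpmMappable`). The denominator is the sample's mappable-read
   total from the metadata, *not* the column sum of the miRNA table; miRNAs
   are a small, variable fraction of a plasma small-RNA library, so the
   genome-wide denominator is the more stable choice. An alternative
   normalization by the geometric mean of an exogenous spike-in
   (ath-miR-159a) and a stable abundant endogenous miRNA (hsa-miR-486-5p)
   is provided (`normalizeSpikeGeomean`); in our experience and in the
   literature it performs slightly worse, and it is not the default.
3. **Aggregate** sequence variants per locus (`sumByLocus`). The
   normalizations are linear, so summation commutes with them; the test
   suite checks this identity on simulated data.

Expression units downstream are therefore *normalized counts per million
mappable reads, summed per locus*. The optional low-expression filter
(`filterLowExpression`) applies a control-group mean threshold, default
3.6 in these normalized units (in a typical plasma exosome cohort this
removes the lowest quarter of loci); whether such a threshold is best
expressed in raw or normalized units is not settled, so the function also
offers an explicit quantile mode.

# Differential-expression screening

`screenAll` reports, per locus, the group arithmetic means, their
case/control ratio, and five p-values: Kruskal–Wallis, Welch's t,
Mann–Whitney, one-way ANOVA, and ANOVA blocked by preparation batch
(two-way fixed effects, F-test on the group term). Count data of this kind
are not reliably normal, so the *screening flag* is defined by the
Kruskal–Wallis test at `alpha = 0.05`; the parametric tests are reported
for comparison.

Numerical conventions, chosen where the field's software differs:

* Kruskal–Wallis uses midranks with tie correction and the chi-squared
  approximation (1 df for two groups); Mann–Whitney uses the two-sided
  normal approximation with tie correction and *no* continuity correction.
  With two groups these are the same statistic, and the suite asserts the
  identity of the two p-values on tie-free data. Exact-enumeration
  p-values differ from the approximation at very small n (by up to ~0.06
  at 3–4 samples per group); the approximation is used uniformly.
* A locus constant across all samples has p = 1 by definition for every
  test; a locus expressed in neither group has an undefined (0/0) ratio,
  reported as `NA` and never flagged.
* No multiple-testing correction is applied at the screening stage. The
  screen is a candidate generator: individual nominal significance is
  given little weight unless a locus also satisfies further statistical or
  biological criteria (effect size, variant-level consistency, membership
  in correlated groups). Benjamini–Hochberg q-values are available behind
  an option for users who want them.

# Differential co-expression and cliques

`spearmanAllPairs` computes Spearman's rho (midranks) for every locus pair
within each group, with two-sided p-values from the t approximation on
n − 2 degrees of freedom; at 35 samples per group, rho ≈ 0.33 sits at
p = 0.05. `categorizePairs` assigns the six standard differential-
correlation categories at thresholds rho > 0.5 and |Δrho| > 0.5:
both-group positive (a), single-group positive with a large difference
(b, c), both-group negative (d), and single-group negative with a large
difference (e, f). Swapping the groups maps b↔c and e↔f, which the suite
checks as a property.

`findCliques` enumerates *maximal* cliques (Bron–Kerbosch with pivoting,
via `igraph`) in the graph induced by one category, reporting every clique
of at least four loci, largest first. Maximal rather than maximum cliques
are reported because overlapping near-cliques are biologically meaningful.
By default an edge requires only rho > 0.5, not additionally p < 0.05:
at the design sample size the two criteria coincide (rho = 0.5 is far
beyond the 5% boundary), and the `requireSignificance` switch restores the
stricter reading for smaller cohorts.

# Feature transform

`log3FoldFeatures` maps expression to bounded fold-change features: per
locus the *grand mean* over all samples (both groups pooled) is the
reference; per sample the fold change against that reference is computed;
fold changes within the open interval (0.90, 1.10) — changes of less than
10% — are rounded to 1; the feature is log base 3 of the fold change,
clamped to [−1, +1]. A 3-fold change saturates the feature. Values exactly
at 0.90 or 1.10 are *not* rounded (the dead zone is open), zero expression
maps to −1 (the clamp of log 0), and an all-zero locus is defined as "no
change" (feature 0). Outside the dead zone the transform is antisymmetric
in the fold change and invariant to jointly rescaling a locus and its
grand mean.

Computing grand means on the full dataset before cross-validation leaks a
small amount of information across folds. The default keeps this protocol
because it is what discovery studies of this design do and because the
grand mean is label-free (the leak does not move the permutation null, as
the honest-null test shows); `foldSafe = TRUE` recomputes the reference
within each training fold for users who want strictly honest estimates.

# Classifier construction

`selectBiomarkerPanel` runs the full model-building procedure:

1. **Cross-validation plan** (`makeCVPlan`): stratified 7-fold partitions
   (5 cases + 5 controls held out per fold at the design size of 35 + 35),
   repeated 10 times for 70 train/test runs; class counts must divide the
   fold count.
2. **Pre-filter**: the 50 features most significant by two-sided
   Mann–Whitney U (ties on p broken by the absolute rank-biserial effect,
   then feature ID, so the ranking is deterministic).
3. **Tree-usage ranking** (`rankByTreeUsage`): one gain-ratio decision
   tree (`fitTree`, C4.5-style: midpoint thresholds, gain-ratio criterion,
   minimum leaf 2, no pruning) per train split; each feature is scored by
   the number of internal nodes it occupies across all trees (a feature
   can count several times in one tree). The 18 best-used features become
   wrapper candidates; features never used score 0 and are not padded in.
4. **Wrapper selection** (`stepwiseSelect`): greedy forward (or backward)
   selection where a step is accepted if it improves the cross-validated
   AUC, with ties broken by MCC (`"auc_then_mcc"`; the looser rule
   "either AUC or MCC improves" is available as `"auc_or_mcc"`). The
   wrapped model is the boosted ensemble below. Every evaluated step is
   recorded in a trace.
5. **Final model** (`fitAdaboostM1`): classical AdaBoost.M1 over depth-1
   threshold stumps, 10 rounds, vote weights ln((1 − ε)/ε), stopping
   early at ε = 0 or ε ≥ 0.5. Stump fitting considers constant rules and
   both polarities, with deterministic tie-breaks so results do not depend
   on feature column order. Confidences are the normalized ensemble
   margin mapped to [0, 1].

The soft-margin linear classifier (`fitLinearMargin`, via libsvm) and the
plain tree are provided as comparison models under the identical CV
protocol. Evaluation (`confusionCounts`, `precisionRecallF1`, `mcc`,
`aucScore`) uses the standard formulas; AUC is computed by the rank
statistic (ties count one half), which equals trapezoidal ROC integration
for tie-free scores — both facts are asserted in the suite. Zero
denominators are defined as 0 (precision, MCC).

In fold-safe mode the *entire* chain — grand means, Mann–Whitney filter,
tree ranking (on an inner plan of 6 folds within the 60-sample training
set), wrapper and final fit — is nested inside each outer fold, and the
reported metrics are purely held-out.

# The synthetic cohort generator

`simulateCohort` draws the dataset the pipeline assumes, with ground truth
(`SimTruth`) for every planted effect:

* **Counts**: negative binomial per locus and sample, expectation
  `baselineCPM × ratio(group) × mappableReads / 1e6`. The NB size
  (dispersion) defaults to 10; no generative model is claimed by typical
  study reports, and this value gives overdispersion clearly beyond
  Poisson while keeping two-fold effects detectable at n = 35. Library
  size is log-normal (median 5 million mappable reads, log-sd 0.4), so a
  library-size effect exists before normalization.
* **Baseline levels**: log-normal on the CPM scale (median 10, log-sd 2),
  spanning below 1 to above 5000 CPM across 465 loci — the observed range
  in plasma exosome cohorts, with a realistic low-expression tail (after
  depth filtering, a control-mean threshold of 3.6 removes on the order of
  a sixth to a quarter of loci). Twenty loci default to fixed control means
  (0.73–5076 CPM) and planted case/control ratios (0.24–3.2), emulating a
  realistic screening outcome; seven additional-ratio variants can be
  planted freely for recovery experiments.
* **Correlated modules**: a Gaussian copula — module members share a
  latent factor within the target group(s) and the latent field is pushed
  through the NB quantile function — so rank correlation is induced while
  marginal count laws are preserved. The module `loading` is the *latent
  pairwise correlation* between members (the shared-variance fraction),
  not the factor coefficient; at loading 0.8 and n = 35 the sample
  Spearman rho of member pairs exceeds 0.5 with high probability, which is
  what "planted clique" should mean operationally. Default modules: a
  25-locus clique present in both groups and two 4-locus single-group
  cliques, all at loading 0.9; the loadings are set high enough
  that the planted cliques survive the rho > 0.5 edge rule, since a
  "planted" structure that thresholds away is not a usable ground truth.
* **IsomiR structure**: each locus's count is split multinomially over
  sequence variants with locus-specific proportions (loci under 10 CPM
  express a single variant, as very low loci do in practice), exercising
  the locus-summation step. A spike-in locus (group-independent, low
  dispersion) and an abundant stable reference locus are always present.
* **Technical replicates** (`simulateTechnicalReplicate`): every count is
  multiplied by log-normal noise of mean 1 and coefficient of variation
  `replicateCv` (default 0.30) and re-rounded. "Expression differing by
  ±30%" is interpreted as the one-standard-deviation (RMS) relative
  difference, which a CV-0.30 law reproduces exactly;
  `replicateAgreement` reports both the RMS and the mean-absolute
  summaries (for a log-normal law the mean-absolute figure is ≈ 0.8 × CV,
  i.e. ~0.24 at CV 0.30).

All randomness is drawn in a fixed documented order from one seed, so a
config + seed pair is bit-reproducible. What the generator does *not*
emulate: read-level artifacts (adapter, alignment, PCR duplication),
batch-correlated expression shifts, heavy-tailed outlier samples, and the
full biological covariance of real plasma miRNA profiles. Passing tests on
synthetic data therefore demonstrate the *procedures* are correct and
calibrated, not that real cohorts will reach any particular performance.

# Problem sizes and runtime choices

The test suite and the acceptance script run everything at the design
size (70 samples × 465 loci) where the property under test concerns the
study conditions: type-I calibration, planted-effect power, panel
recovery, replicate noise, and the label-permuted null. For the fold-safe
null the outer plan uses 2 repeats (14 held-out estimates per seed, 10
seeds — 140 estimates in total), which bounds the Monte-Carlo error of the
mean AUC well below the width of the acceptance band while keeping the
nested procedure affordable. Unit-level properties (oracles, identities,
edge cases) use small explicit inputs.

# Interfaces

The package's functions, `runFull()` (which writes the complete TSV/JSON
report bundle with seeds and a config hash in every header) and this
vignette are the supported interface; no shell entry point is shipped,
as an R analyst drives these stages from scripts or interactive sessions.

# Known limitations

* Exact-permutation p-values are not offered; at very small group sizes
  the normal/chi-squared approximations drift (documented above).
* The J48-style tree implements gain-ratio splitting with a minimum leaf
  size but no confidence-based pruning or subtree raising; with shallow,
  pre-screened feature sets, pruning has no practical effect here.
* The wrapper's criterion comparisons use a fixed numeric tolerance; with
  very small CV plans the criterion surface is discrete and the selected
  set can be seed-sensitive — by design, the trace records every decision.
* Performance figures from the default (non-fold-safe) protocol inherit
  the selection optimism of discovery studies; use `foldSafe = TRUE` for
  honest estimates.
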