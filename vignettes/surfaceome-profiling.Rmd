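---
title: "Profiling the expressed surfaceome from normalized transcriptomic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the expressed surfaceome from normalized transcriptomic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfaceomics)
```

## The problem and the model

Proteins on the tumor cell surface — the *surfaceome* — are the most
accessible pool of biomarkers and drug targets, yet for rare cancers such
as penile squamous cell carcinoma there is little data describing which
surface proteins are actually expressed. `surfaceomics` infers an
"expressed surfaceome" from ordinary normalized expression matrices
(microarray, RNA-seq after variance-stabilizing transformation, or
translatome arrays) combined with a catalogue of predicted cell-surface
proteins (a SURFY-like table of ~2886 genes annotated with Almén
functional classes and GlycoMine glycosylation-motif calls).

The inference is deliberately nonparametric. For a consolidated
genes-by-samples matrix:

1. within each sample, every gene receives its empirical-CDF quantile
   $q_{gs} = \frac{1}{n}\,\#\{g' : x_{g's} \le x_{gs}\}$ and its ascending
   rank (average rank for ties);
2. per gene, the quantiles and ranks are summarized by their median across
   samples;
3. the median quantile is binned into quartile tiers with the partition
   $(0, .25] \to Q1$, $(.25, .5] \to Q2$, $(.5, .75] \to Q3$,
   $(.75, 1] \to Q4$;
4. the **expressed surfaceome** of the dataset is the set of catalogued
   surface genes in Q4 of *whole-transcriptome* expression.

Because only within-sample order matters, the procedure is invariant to
any strictly increasing per-sample transform, which is what lets
differently normalized platforms be combined by set intersection of their
Q4 surfaceomes rather than by numeric merging. No imputation is done:
a gene missing from one platform simply cannot enter that dataset's Q4.

Downstream statistics are conventional: Pearson chi-squared (without
continuity correction) for glycosylation-motif presence between tiers,
per-gene two-sided Welch t-tests between HPV-negative and HPV-positive
samples with per-class "n different / n total" summaries, per-class
druggability tallies against a drug–target map, Fisher's exact test and
Wilcoxon rank-sum tests for clinicopathologic tables and
immunohistochemistry (IHC) compartments, and Kaplan–Meier curves with
log-rank tests after median dichotomization of a marker gene.

## Tunable parameters that matter

* `alpha` (default 0.05) — the unadjusted per-gene significance threshold
  of the HPV screen. The per-class difference tables are descriptive
  (fractions of genes crossing `alpha`), so no multiplicity correction is
  applied by default; `alpha` is recorded with every result.
* `expressed_tier` (default `"Q4"`) — which quartile defines "expressed".
  Q4 encodes the assumption that the top 25% of relative expression is
  the robustly translated, surface-displayed fraction.
* The quartile boundaries themselves are fixed by the ecdf range:
  half-open on the left and closed on the right, so a median quantile of
  exactly 0.75 is Q3 and the maximum quantile in each sample is exactly 1.

## Numerical conventions

These conventions are deterministic and pinned by tests:

* **ecdf ties** share the upper value (`rank(..., ties.method = "max")/n`),
  matching the standard ecdf step function evaluated at the data points.
* **Ranks** ascend (1 = lowest) with average ties. The median rank is
  reported but plays no role in tiering; the median quantile alone drives
  Q1–Q4.
* **Replicate collapsing** averages technical duplicates (arithmetic mean
  per gene); groups mixing HPV statuses are rejected as metadata errors.
* **Reporter consolidation** keeps, per gene symbol, the reporter with
  the highest median expression across samples; exact ties are broken by
  the lexicographically smallest reporter id so results cannot depend on
  file order.
* **Medians over an even number of samples** are the midpoint of the two
  central values.
* **Degenerate genes** (zero variance in both HPV groups) are reported
  with p = 1 rather than dropped, so per-class denominators always equal
  the number of genes screened.
* **Chi-squared without continuity correction**: on the published motif
  table the uncorrected test reproduces the printed p = 0.024 from the
  table's own counts, whereas the Yates-corrected value would be ≈ 0.04;
  a zero marginal is refused with a pointer to the exact test.
* **Median split** assigns ties at the median to "low", so an even cohort
  of distinct values splits in half; a constant vector cannot be split
  and is an error.
* **Kaplan–Meier median OS** is the earliest time at which the survival
  estimate is ≤ 0.5 ("not reached" → `NA`, serialized as `null` in JSON
  and `NR` in TSV). This differs from `survfit`'s plateau-midpoint
  convention only when the curve sits exactly at 0.5 over an interval.
* **IHC compartment comparison** is unpaired by default (membrane and
  nuclear scores treated as independent groups); a paired signed-rank
  variant is available behind `paired = TRUE`.
* The p16-by-HPV association is computed on the 2×2 excluding `Unknown`
  calls; the Unknown row stays in the descriptive table.

## What the synthetic generator emulates

`simulationConfig()` fixes the study conditions; all generators are pure
functions of it (one global seed, deterministic per-generator
substreams, so adding a generator never perturbs the others).

* **Catalogue**: 2886 surface genes inside a 20,000-gene transcriptome;
  Almén main classes drawn with probabilities 0.25 / 0.18 / 0.07 / 0.16 /
  0.34 (receptors, transporters, enzymes, miscellaneous, unclassified),
  with receptor and transporter subclasses (GPCR, IG, SCAR, SLC,
  channels) in roughly the published subclass ratios.
* **Expression** is generated directly on a normalized log scale —
  Gaussian per-gene baselines (mean 6, SD 2) plus sample noise — not as
  counts, because every pipeline stage operates post-normalization.
  A planted 15% of surfaceome genes is shifted up by 2.5 baseline SDs;
  this is the "expressed surfaceome" the pipeline should recover, and
  recovery sensitivity ≥ 0.9 is part of the acceptance suite.
* **Cell lines**: five HPV-negative lines arrayed in duplicate; the two
  duplicates share the gene baseline and a per-line effect (SD 0.3) and
  differ by technical noise (SD 0.3), giving duplicate correlations
  above 0.95.
* **Tumors**: 18 samples, 10 HPV-positive; 10% of surfaceome genes get a
  ±2 within-group-SD HPV shift (detectable by a Welch test at n = 8 vs 10
  with power > 0.8); all HPV-positive tumors are p16-positive; overall
  survival is exponential with baseline hazard 0.02/month, a log hazard
  ratio of log 4 for tumors above the marker gene's median expression,
  and independent exponential censoring tuned to ~30% censoring.
* **Drug map**: per-class Bernoulli hit rates of 23.4 / 22.5 / 21.2 /
  1.45 / 6.3 percent with `1 + Poisson(2)` compounds per hit, mirroring
  the published per-class druggability.
* **IHC**: 12 tumors × 3 markers × 2 compartments with high membrane and
  low nuclear percent positivity (FGFR1 given the smallest gap).

What the generator does **not** emulate: count-level sampling noise,
platform-specific probe effects, tumor purity, correlated gene modules,
or HPV genotype diversity. Passing tests therefore demonstrate that the
statistical machinery is correct and well calibrated under the assumed
generative model, not that the biological findings of any particular
cohort are reproduced — dataset-dependent gene counts require the
original data and are explicitly out of scope.

Alongside the stochastic generators, `fixturePaperTables()` rebuilds,
deterministically, gene-level and patient-level tables whose marginals
equal published contingency and druggability tables exactly; the test
suite and the acceptance script recompute the published statistics
(motif-test p-values, the p16 Fisher p, mean drugs per target and percent
of targets with drugs) from those fixtures through the ordinary analysis
functions.

## Design choices on genuinely open points

* Quartiles are computed over **all** genes of a dataset and surface
  genes are then binned — not quartiles within the surfaceome subset.
  This is why tier sizes are unequal (e.g. 239 vs 497 in the published
  motif table) and is the reading consistent with those printed counts.
* Drug–target matching is done by **gene symbol** (case-sensitive after
  whitespace trimming); a dialect column-map on read handles
  platform-specific headers, and no identifier-translation service is
  built in.
* "Total drugs" per class sums compound-set sizes per target without
  cross-target deduplication; this reproduces the arithmetic relations
  among the published druggability columns (85/115 = 0.74,
  27/115 = 23.5%).
* A motif is "present" if the gene has at least one called site of that
  class; the catalogue stores only the collapsed boolean.
* The multi-set overlap report returns every Venn region, so either
  reading of a "validation overlap" (intersecting validation cohorts
  with the main intersection, or with each other first) can be computed
  from it.
* The pipeline is driven by exported functions plus a JSON run
  configuration (`runConfig()` / `runPipeline()`); per-stage functions
  are the "subcommands".

## Problem sizes used by the test suite

Unit tests run on matrices of tens to a few thousand genes with
brute-force oracles (O(n²) quantile counting, exhaustive rank-sum and
hypergeometric enumeration, hand-coded Welch and product-limit
formulas). Calibration checks use 2000 null replicates for the Welch
test, 500 for log-rank power, 200 for screen power, and 50 full-size
(20,000-gene) simulation replicates for planted-surfaceome recovery —
sizes chosen so the whole suite completes in a couple of minutes while
keeping Monte-Carlo error well inside the asserted confidence bands.

## Known limitations

* Tier membership near quartile boundaries is sensitive to platform
  coverage: adding or removing genes moves every quantile slightly.
* The HPV screen is a per-gene Welch test on normalized values; it does
  not borrow strength across genes (no moderation/shrinkage) and applies
  no multiplicity correction by default.
* Survival analysis is a two-group log-rank comparison; no Cox
  regression or covariate adjustment is provided.
* The published cohort-dependent gene counts (e.g. 1528 / 497 / 452 /
  123) and survival medians require the original datasets and are not
  reproduced by the synthetic conditions.
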