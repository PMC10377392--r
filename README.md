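# surfaceomics

Infers the **expressed surfaceome** — the set of cell-surface genes in the
top quartile of whole-transcriptome expression — from normalized expression
matrices, and runs the downstream statistics used to characterize it:
functional-class and glycosylation-motif breakdowns, HPV-status differential
screening, druggability summaries against a drug–target map, and clinical
association / survival analysis. It is aimed at researchers profiling
surface-accessible biomarker and drug-target candidates from bulk
transcriptomic or translatomic data, particularly in rare cancers where
patient-level resources are scarce.

## The method

For a consolidated genes × samples matrix, each gene *g* in sample *s*
receives its empirical-CDF quantile

&nbsp;&nbsp;&nbsp;&nbsp;*q₍gs₎* = #{g′ : x₍g′s₎ ≤ x₍gs₎} / n,

quantiles are summarized per gene by their median across samples, and the
median quantile is binned into quartile tiers Q1–Q4 by the partition
(0, .25] → Q1, …, (.75, 1] → Q4. The expressed surfaceome of a dataset is
the intersection of its Q4 tier with a SURFY-like surface-protein
catalogue; expressed surfaceomes from different platforms are combined by
set intersection, which is valid because the quantile transform is
invariant to any strictly increasing per-sample normalization.

On top of that: Pearson chi-squared tests (uncorrected) compare
glycosylation-motif presence between expression tiers; per-gene two-sided
Welch t-tests screen for HPV-dependent expression with per-class
"n different / n total" summaries; per-Almén-class druggability tallies
count targets with ≥ 1 mapped compound; Fisher exact / Wilcoxon rank-sum
tests summarize clinicopathologic tables and IHC compartments; and
Kaplan–Meier curves with log-rank tests compare survival after median
dichotomization of a marker gene. A synthetic-data generator
(`simulationConfig()` + `simulate*()`) produces complete input bundles with
the statistical structure the analysis assumes, and `fixturePaperTables()`
deterministically rebuilds tables whose marginals match published
contingency and druggability summaries exactly.

## Worked example

```r
library(surfaceomics)

cfg       <- simulationConfig(seed = 42)          # study-scale conditions
catalogue <- simulateCatalogue(cfg)               # 2886-gene surface catalogue
cells     <- collapseReplicates(simulateCellLines(cfg))
sm        <- summarizeGenes(cells)                # median rank/quantile + tier
es        <- expressedSurfaceome(sm, catalogue, "cell_lines")
es
#> ExpressedSurfaceome [cell_lines]: 990 genes (tier Q4)

tumors <- simulateTumors(cfg)
es_t   <- expressedSurfaceome(summarizeGenes(tumors$dataset), catalogue, "tumors")
shared <- intersectExpressed(es, es_t)
length(shared)
#> [1] 515

classBreakdown(shared, catalogue, "main")
#>           class count   percent percent_display
#> 1  Unclassified   175 33.980583              34
#> 2     Receptors   136 26.407767              26
#> 3  Transporters    93 18.058252              18
#> 4 Miscellaneous    74 14.368932              14
#> 5       Enzymes    37  7.184466               7

mt <- motifTierTest(quartileSubsets(sm, catalogue, "Q1"),
                    quartileSubsets(sm, catalogue, "Q4"), catalogue, "O")
mt$p_value
#> [1] 0.002986507

res <- survivalByMedianSplit(tumors$clinical, tumors$dataset, markerGene(cfg))
res$summary
#>   group n events median_os
#> 1   low 9      3     80.63
#> 2  high 9      8     11.83
res$logrank_p
#> [1] 0.004952056
```

Reading the output: 990 of the 2886 catalogued surface genes sit in the
cell lines' top expression quartile; 515 of them are also top-quartile in
the tumor cohort and form the shared expressed surfaceome, about a quarter
of which are receptors and 18% transporters. O-linked glycosylation motifs
are enriched in the top tier relative to the bottom tier (p ≈ 0.003), and
tumors with marker-gene expression above the cohort median have markedly
shorter overall survival (median 11.8 months vs 80.6, log-rank p ≈ 0.005)
— the planted hazard ratio of the simulation being recovered.

The same stages run end-to-end from files via `runConfig()` +
`runPipeline()`, which writes every intermediate TSV and a JSON report;
`simulateInputBundle()` writes a matching input directory.

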