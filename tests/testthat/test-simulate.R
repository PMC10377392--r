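test_that("catalogue generator hits its design marginals deterministically", {
  cfg <- simulationConfig(seed = 101)  # full-size study conditions
  cat1 <- simulateCatalogue(cfg)
  expect_equal(sum(catalogueTable(cat1)$is_surfaceome), 2886L)
  expect_equal(length(cat1), 20000L)

  # class counts within a joint 99% CI (Bonferroni over five classes)
  ann <- catalogueTable(cat1)
  tab <- table(ann$almen_main[ann$is_surfaceome])
  for (cl in names(cfg$class_proportions)) {
    p <- cfg$class_proportions[[cl]]
    half <- qnorm(1 - 0.01 / 10) * sqrt(p * (1 - p) * 2886)
    expect_lt(abs(tab[[cl]] - 2886 * p), half + 1)
  }

  # seed-fixed rerun is identical; different seed differs
  expect_identical(catalogueTable(simulateCatalogue(cfg)), ann)
  cat2 <- simulateCatalogue(simulationConfig(seed = 102))
  expect_false(identical(catalogueTable(cat2), ann))
})

test_that("cell-line generator plants recoverable high expression", {
  cfg <- small_sim_config(seed = 103)
  ed <- simulateCellLines(cfg)
  si <- sampleInfo(ed)
  expect_equal(ncol(ed), 10L)
  expect_true(all(si$hpv_status == "neg"))
  expect_equal(length(unique(si$replicate_group)), 5L)

  # technical duplicates correlate strongly (shared gene + line effects)
  m <- exprValues(ed)
  for (g in unique(si$replicate_group)) {
    cols <- which(si$replicate_group == g)
    expect_gt(cor(m[, cols[1]], m[, cols[2]]), 0.95)
  }

  # planted-high genes rank above the rest on average
  sm <- summarizeGenes(collapseReplicates(ed))
  planted <- plantedHighGenes(cfg)
  mq <- setNames(sm$median_quantile, sm$symbol)
  expect_gt(mean(mq[planted]), mean(mq[setdiff(names(mq), planted)]))

  expect_identical(exprValues(simulateCellLines(cfg)), m)
})

test_that("tumor generator produces the configured cohort structure", {
  cfg <- small_sim_config(seed = 104)
  tum <- simulateTumors(cfg)
  clin <- tum$clinical
  expect_equal(nrow(clin), 18L)
  expect_equal(sum(clin$hpv_status == "pos"), 10L)
  expect_true(all(clin$p16[clin$hpv_status == "pos"] == "Positive"))
  expect_true(all(is.finite(clin$os_months) & clin$os_months >= 0))

  # planted HPV-effect genes are recovered by the screen with power > 0.8
  eff <- attr(tum, "hpv_effect_genes")
  scr <- hpvScreen(tum$dataset, eff, alpha = 0.05)
  expect_gt(mean(scr$significant), 0.8)

  # under the null HPV effect the screen stays calibrated
  cfg0 <- small_sim_config(seed = 105, hpv_effect_fraction = 0)
  tum0 <- simulateTumors(cfg0)
  scr0 <- hpvScreen(tum0$dataset, surfaceomeSymbols(simulateCatalogue(cfg0)))
  expect_lt(mean(scr0$significant), 0.10)
})

test_that("null marker effect keeps the log-rank near its nominal level", {
  # survival_log_hr = 0: rejection rate approximately 0.05 over replicates
  rejections <- 0L
  n_rep <- 120
  for (i in seq_len(n_rep)) {
    cfg <- simulationConfig(seed = 2000 + i, n_genes = 60, n_surfaceome = 20,
                            survival_log_hr = 0)
    tum <- simulateTumors(cfg)
    res <- survivalByMedianSplit(tum$clinical, tum$dataset, markerGene(cfg))
    if (res$logrank_p < 0.05) rejections <- rejections + 1L
  }
  # 99% binomial CI around 0.05 for n = 120 reaches ~0.11
  expect_lt(rejections / n_rep, 0.12)
})

test_that("drug-table generator follows the per-class hit rates", {
  cfg <- simulationConfig(seed = 106)  # full-size for tight CIs
  cat1 <- simulateCatalogue(cfg)
  dm <- simulateDrugTable(cfg, cat1)
  ann <- catalogueTable(cat1)
  ann <- ann[ann$is_surfaceome, ]
  hit <- ann$symbol %in% names(drugEntries(dm))
  # joint 99% CI: Bonferroni across the five classes
  for (cl in names(cfg$drug_rate)) {
    in_cl <- !is.na(ann$almen_main) & ann$almen_main == cl
    n <- sum(in_cl)
    p <- cfg$drug_rate[[cl]]
    half <- qnorm(1 - 0.01 / 10) * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(hit[in_cl]) - p), half + 1 / n)
  }
  expect_true(all(lengths(drugEntries(dm)) >= 1))

  cfg0 <- small_sim_config(seed = 107,
                           drug_rate = c(Receptors = 0, Transporters = 0,
                                         Enzymes = 0, Miscellaneous = 0,
                                         Unclassified = 0))
  expect_equal(length(simulateDrugTable(cfg0, simulateCatalogue(cfg0))), 0L)

  expect_identical(drugEntries(simulateDrugTable(cfg, cat1)),
                   drugEntries(dm))
})

test_that("IHC generator separates membrane from nuclear staining", {
  cfg <- small_sim_config(seed = 108)
  ihc <- simulateIHC(cfg)
  expect_equal(nrow(ihc), 72L)  # 12 samples x 3 markers x 2 compartments
  expect_equal(sort(unique(ihc$marker)), c("CD147", "FGFR1", "MCT1"))
  for (mk in unique(ihc$marker)) {
    mem <- ihc$percent_positive[ihc$marker == mk &
                                  ihc$compartment == "membrane"]
    nuc <- ihc$percent_positive[ihc$marker == mk &
                                  ihc$compartment == "nuclear"]
    expect_gt(mean(mem), mean(nuc))
  }
  expect_identical(ihc$percent_category, percentCategory(ihc$percent_positive))
})

test_that("input bundles round-trip losslessly and are reproducible", {
  cfg <- small_sim_config(seed = 109)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulateInputBundle(cfg, d1)
  p2 <- simulateInputBundle(cfg, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), label = f)
  }

  # every file reads back through the package's own readers
  cat_rt <- readCatalogue(p1$catalogue)
  expect_identical(catalogueTable(cat_rt),
                   catalogueTable(simulateCatalogue(cfg)))
  cl <- readExpressionDataset(p1$cell_lines, p1$cell_line_samples)
  expect_equal(exprValues(cl), exprValues(simulateCellLines(cfg)),
               tolerance = 1e-10)
  expect_identical(sampleInfo(cl)$replicate_group,
                   sampleInfo(simulateCellLines(cfg))$replicate_group)
  tum <- readExpressionDataset(p1$tumors, p1$tumor_samples)
  expect_equal(dim(tum), c(cfg$n_genes, cfg$n_tumors))
  clin <- readClinicalTable(p1$clinical)
  expect_identical(clin$os_event, simulateTumors(cfg)$clinical$os_event)
  drugs <- readDrugTable(p1$drugs)
  expect_identical(drugEntries(drugs),
                   drugEntries(simulateDrugTable(cfg, cat_rt)))
  ihc <- readIHCTable(p1$ihc)
  expect_equal(nrow(ihc), 72L)
})
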