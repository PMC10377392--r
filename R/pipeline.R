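#' Pipeline run configuration
#'
#' Collects input paths and analysis knobs for [runPipeline()]. A
#' configuration can also be read from a JSON file with the same field
#' names via [readRunConfig()].
#'
#' @param catalogue path to the surfaceome catalogue TSV.
#' @param datasets named list of expression datasets; each element a list
#'   with `expr` and `samples` paths (see [readExpressionDataset()]). The
#'   first dataset anchors the motif tier comparison; the dataset containing
#'   both HPV groups is used for the differential screen and survival.
#' @param drugs optional path to the drug-target TSV.
#' @param clinical optional path to the clinical TSV.
#' @param ihc optional path to the IHC TSV.
#' @param out_dir output directory for intermediate TSVs and the JSON
#'   report.
#' @param alpha significance threshold for the differential screen.
#' @param expressed_tier quartile tier defining "expressed" (default `Q4`).
#' @param survival_genes gene symbols for median-split survival comparisons
#'   (requires `clinical` and a dataset whose samples are the patients).
#' @param seed seed for any resampling fallback (Monte-Carlo Fisher).
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(catalogue, datasets, drugs = NULL, clinical = NULL,
                      ihc = NULL, out_dir = tempfile("surfrun"),
                      alpha = 0.05,
                      expressed_tier = c("Q4", "Q1", "Q2", "Q3"),
                      survival_genes = NULL, seed = 1L) {
  expressed_tier <- match.arg(expressed_tier)
  cfg <- list(catalogue = catalogue, datasets = datasets, drugs = drugs,
              clinical = clinical, ihc = ihc, out_dir = out_dir,
              alpha = alpha, expressed_tier = expressed_tier,
              survival_genes = survival_genes, seed = as.integer(seed))
  if (length(cfg$datasets) < 1) stop("at least one expression dataset is required")
  if (is.null(names(cfg$datasets)) || any(!nzchar(names(cfg$datasets))))
    stop("datasets must be a named list")
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname runConfig
#' @param path path to a JSON file whose fields mirror the [runConfig()]
#'   arguments.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  raw$datasets <- lapply(raw$datasets, function(d) list(expr = d$expr, samples = d$samples))
  do.call(runConfig, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full surfaceome profiling pipeline
#'
#' Executes, in order: per-dataset replicate collapsing, symbol
#' consolidation and gene summarization; expressed-surfaceome derivation and
#' functional-class breakdown per dataset; cross-dataset intersection;
#' glycosylation-motif tier tests (bottom vs top quartile of the first
#' dataset); the HPV differential screen with per-class summaries (on the
#' dataset having both HPV groups); druggability summarization; and the
#' clinical statistics (cohort table, p16-by-HPV Fisher test, IHC
#' compartment comparisons, median-split survival). Every intermediate table
#' is written as TSV under `out_dir` together with a machine-readable
#' `report.json`. A stage failure aborts the run naming the stage; partial
#' outputs are retained.
#'
#' @param config a [runConfig()] (or path to a JSON run configuration).
#' @return the report, invisibly, as a named list (also serialized to
#'   `out_dir/report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(alpha = config$alpha, expressed_tier = config$expressed_tier)

  catalogue <- .stage("read_catalogue", readCatalogue(config$catalogue))

  summaries <- list()
  datasets <- list()
  expressed <- list()
  report$expressed_counts <- list()
  report$class_breakdowns <- list()
  for (ds_name in names(config$datasets)) {
    ds_cfg <- config$datasets[[ds_name]]
    ds <- .stage(paste0("read_dataset:", ds_name),
                 readExpressionDataset(ds_cfg$expr, ds_cfg$samples))
    ds <- .stage(paste0("collapse_replicates:", ds_name),
                 collapseReplicates(ds))
    rd <- SummarizedExperiment::rowData(ds)
    if ("symbol" %in% colnames(rd))
      ds <- .stage(paste0("consolidate:", ds_name),
                   suppressMessages(consolidateToSymbols(ds)))
    datasets[[ds_name]] <- ds
    sm <- .stage(paste0("summarize:", ds_name), summarizeGenes(ds))
    summaries[[ds_name]] <- sm
    .write_tsv(sm, out(paste0("summaries_", ds_name, ".tsv")))
    genes <- .stage(paste0("expressed:", ds_name),
                    quartileSubsets(sm, catalogue, config$expressed_tier))
    expressed[[ds_name]] <- genes
    .write_tsv(data.frame(symbol = genes),
               out(paste0("expressed_", ds_name, ".tsv")))
    bd <- classBreakdown(genes, catalogue, "main")
    report$class_breakdowns[[ds_name]] <- bd
    .write_tsv(bd, out(paste0("class_breakdown_", ds_name, ".tsv")))
    report$expressed_counts[[ds_name]] <- length(genes)
  }

  inter <- .stage("intersect", Reduce(intersectExpressed, expressed))
  .write_tsv(data.frame(symbol = inter), out("intersection.tsv"))
  report$intersection_size <- length(inter)
  if (length(expressed) >= 2) {
    ov <- multiOverlap(expressed)
    .write_tsv(ov$regions, out("overlap_regions.tsv"))
    report$overlap_regions <- ov$regions
  }
  report$intersection_breakdown <-
    classBreakdown(inter, catalogue, "main")

  # motif tier tests on the first dataset: bottom vs top quartile
  first <- names(config$datasets)[1]
  q1 <- quartileSubsets(summaries[[first]], catalogue, "Q1")
  q4 <- quartileSubsets(summaries[[first]], catalogue, "Q4")
  if (length(q1) > 0 && length(q4) > 0) {
    motifs <- c("O", "C", "noncyt_nxst")
    mt <- lapply(motifs, function(m)
      .stage(paste0("motif_test:", m), motifTierTest(q1, q4, catalogue, m)))
    report$motif_tests <- data.frame(
      motif = motifs,
      statistic = vapply(mt, `[[`, numeric(1), "statistic"),
      p_value = vapply(mt, `[[`, numeric(1), "p_value"))
    .write_tsv(report$motif_tests, out("motif_tests.tsv"))
  }

  # differential screen on the dataset with both HPV groups
  hpv_ds <- NULL
  for (ds_name in names(datasets)) {
    hs <- sampleInfo(datasets[[ds_name]])$hpv_status
    if (sum(hs == "neg") >= 2 && sum(hs == "pos") >= 2) {
      hpv_ds <- ds_name
      break
    }
  }
  if (!is.null(hpv_ds)) {
    scr <- .stage("hpv_screen",
                  suppressMessages(hpvScreen(datasets[[hpv_ds]], inter,
                                             alpha = config$alpha)))
    .write_tsv(scr, out("hpv_screen.tsv"))
    for (lv in c("main", "sub")) {
      cds <- classDifferenceSummary(scr, catalogue, lv)
      .write_tsv(cds, out(paste0("hpv_class_summary_", lv, ".tsv")))
      report$hpv_summary[[lv]] <- cds
    }
    report$hpv_summary$dataset <- hpv_ds
    report$hpv_summary$n_tested <- nrow(scr)
    report$hpv_summary$n_significant <- sum(scr$significant)
  }

  if (!is.null(config$drugs)) {
    drugs <- .stage("read_drugs", suppressWarnings(readDrugTable(config$drugs)))
    dg <- .stage("druggability",
                 suppressWarnings(druggabilitySummary(inter, catalogue, drugs)))
    .write_tsv(dg, out("druggability.tsv"))
    report$druggability <- dg
  }

  if (!is.null(config$clinical)) {
    clin <- .stage("read_clinical", readClinicalTable(config$clinical))
    ct <- .stage("cohort_table", cohortTable(clin))
    .write_tsv(ct, out("cohort_table.tsv"))
    report$clinical_tests <- ct
    known <- clin[clin$p16 != "Unknown", , drop = FALSE]
    tab <- table(factor(known$hpv_status, levels = c("neg", "pos")),
                 factor(known$p16, levels = c("Negative", "Positive")))
    fe <- .stage("p16_fisher", suppressWarnings(fisherExact2x2(as.matrix(tab))))
    report$p16_hpv_fisher_p <- fe$p_value
    if (!is.null(config$survival_genes) && !is.null(hpv_ds)) {
      surv <- lapply(config$survival_genes, function(g) {
        res <- .stage(paste0("survival:", g),
                      survivalByMedianSplit(clin, datasets[[hpv_ds]], g))
        list(gene = g, groups = res$summary,
             logrank_p = res$logrank_p,
             logrank_statistic = res$logrank_statistic)
      })
      names(surv) <- config$survival_genes
      report$survival <- surv
    }
  }

  if (!is.null(config$ihc)) {
    ihc <- .stage("read_ihc", readIHCTable(config$ihc))
    res <- lapply(unique(ihc$marker), function(mk)
      .stage(paste0("ihc:", mk), ihcCompartmentCompare(ihc, mk)))
    report$ihc_tests <- data.frame(
      marker = vapply(res, `[[`, character(1), "marker"),
      median_membrane = vapply(res, `[[`, numeric(1), "median_membrane"),
      median_nuclear = vapply(res, `[[`, numeric(1), "median_nuclear"),
      p_value = vapply(res, `[[`, numeric(1), "p_value"))
    .write_tsv(report$ihc_tests, out("ihc_tests.tsv"))
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(report)
}
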