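#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
NULL

.ALMEN_MAIN <- c("Receptors", "Transporters", "Enzymes", "Miscellaneous",
                 "Unclassified")
.HPV_LEVELS <- c("neg", "pos", "unknown")
.MOTIF_COLS <- c("glycomineO_present", "glycomineC_present",
                 "noncyt_nxst_present")
.QUARTILES <- c("Q1", "Q2", "Q3", "Q4")

#' Surfaceome annotation catalogue
#'
#' Holds one row per gene: symbol, cell-surface membership, Almen main and
#' subclass protein-family categorization, and collapsed glycosylation-motif
#' presence flags (O-linked, C-linked/mannosylation, and non-cytosolic
#' N-linked at the N-X-S/T sequon). "Present" means the gene carries at least
#' one called site of the motif class; the catalogue stores only the
#' collapsed boolean. Non-surface genes carry no annotation; surface genes
#' must have all three motif flags defined.
#'
#' @slot annotations a `data.frame` with columns `symbol`, `is_surfaceome`,
#'   `almen_main`, `almen_sub`, `glycomineO_present`, `glycomineC_present`,
#'   `noncyt_nxst_present`.
#' @export
setClass("SurfaceomeCatalogue", slots = c(annotations = "data.frame"))

setValidity("SurfaceomeCatalogue", function(object) {
  ann <- object@annotations
  need <- c("symbol", "is_surfaceome", "almen_main", "almen_sub", .MOTIF_COLS)
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0)
    return(paste0("missing catalogue column(s): ", paste(miss, collapse = ", ")))
  if (any(is.na(ann$symbol) | !nzchar(ann$symbol)))
    return("empty gene symbol(s) in catalogue")
  dup <- unique(ann$symbol[duplicated(ann$symbol)])
  if (length(dup) > 0)
    return(paste0("duplicated gene symbol(s): ",
                  paste(utils::head(dup, 5L), collapse = ", ")))
  if (any(is.na(ann$is_surfaceome)))
    return("is_surfaceome must be TRUE/FALSE for every gene")
  bad_main <- !is.na(ann$almen_main) & !(ann$almen_main %in% .ALMEN_MAIN)
  if (any(bad_main))
    return(paste0("unknown Almen main class: ",
                  paste(unique(ann$almen_main[bad_main]), collapse = ", ")))
  if (any(!is.na(ann$almen_sub) & is.na(ann$almen_main)))
    return("almen_sub set without almen_main")
  surf <- ann$is_surfaceome
  for (m in .MOTIF_COLS) {
    if (any(surf & is.na(ann[[m]])))
      return(paste0(m, " must be defined for every surfaceome gene"))
    if (any(!surf & !is.na(ann[[m]])))
      return(paste0(m, " must be absent for non-surfaceome genes"))
  }
  if (any(!surf & (!is.na(ann$almen_main) | !is.na(ann$almen_sub))))
    return("Almen annotation present on non-surfaceome gene(s)")
  TRUE
})

#' Construct a SurfaceomeCatalogue
#'
#' @param annotations a `data.frame`; required columns `symbol` and
#'   `is_surfaceome`, the Almen and motif columns are added as `NA` when
#'   absent. Symbols are whitespace-trimmed and must be unique.
#' @return a validated [SurfaceomeCatalogue-class] object.
#' @examples
#' cat <- SurfaceomeCatalogue(data.frame(
#'   symbol = c("BSG", "FGFR1", "ACTB"),
#'   is_surfaceome = c(TRUE, TRUE, FALSE),
#'   almen_main = c("Unclassified", "Receptors", NA),
#'   glycomineO_present = c(TRUE, FALSE, NA),
#'   glycomineC_present = c(FALSE, FALSE, NA),
#'   noncyt_nxst_present = c(TRUE, TRUE, NA)))
#' surfaceomeSymbols(cat)
#' @export
SurfaceomeCatalogue <- function(annotations) {
  annotations <- as.data.frame(annotations)
  annotations$symbol <- trimws(as.character(annotations$symbol))
  annotations$is_surfaceome <- as.logical(annotations$is_surfaceome)
  for (col in c("almen_main", "almen_sub")) {
    if (is.null(annotations[[col]])) annotations[[col]] <- NA_character_
    annotations[[col]] <- as.character(annotations[[col]])
    annotations[[col]][!is.na(annotations[[col]]) &
                         !nzchar(annotations[[col]])] <- NA_character_
  }
  for (col in .MOTIF_COLS) {
    if (is.null(annotations[[col]])) annotations[[col]] <- NA
    annotations[[col]] <- as.logical(annotations[[col]])
  }
  rownames(annotations) <- NULL
  new("SurfaceomeCatalogue", annotations = annotations)
}

#' @rdname catalogue-accessors
#' @export
setMethod("catalogueTable", "SurfaceomeCatalogue", function(x, ...) x@annotations)

#' @rdname catalogue-accessors
#' @export
setMethod("surfaceomeSymbols", "SurfaceomeCatalogue", function(x, ...) {
  ann <- x@annotations
  ann$symbol[ann$is_surfaceome]
})

#' @describeIn SurfaceomeCatalogue number of catalogued genes.
#' @param x a `SurfaceomeCatalogue`.
#' @export
setMethod("length", "SurfaceomeCatalogue", function(x) nrow(x@annotations))

setMethod("show", "SurfaceomeCatalogue", function(object) {
  ann <- object@annotations
  cat("SurfaceomeCatalogue with", nrow(ann), "genes (",
      sum(ann$is_surfaceome), "surfaceome )\n")
  tab <- table(factor(ann$almen_main[ann$is_surfaceome], levels = .ALMEN_MAIN))
  cat("  Almen main classes:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

#' Drug-target map
#'
#' A mapping from gene symbol to a deduplicated set of compound identifiers,
#' as obtained by cross-referencing a drug database. Symbols need not all
#' exist in the annotation catalogue; unmatched symbols are ignored (with a
#' warning) when the map is summarized.
#'
#' @slot entries named list; each element a character vector of compound ids.
#' @export
setClass("DrugTargetMap", slots = c(entries = "list"))

setValidity("DrugTargetMap", function(object) {
  e <- object@entries
  if (length(e) > 0 && (is.null(names(e)) || any(!nzchar(names(e)))))
    return("entries must be named by gene symbol")
  if (any(duplicated(names(e))))
    return("duplicated symbols in drug map")
  if (!all(vapply(e, is.character, logical(1))))
    return("compound sets must be character vectors")
  if (any(vapply(e, anyDuplicated, integer(1)) > 0))
    return("compound sets must be deduplicated")
  TRUE
})

#' Construct a DrugTargetMap
#'
#' @param entries named list of character vectors (symbol -> compound ids);
#'   compound sets are deduplicated and sorted.
#' @return a validated [DrugTargetMap-class].
#' @export
DrugTargetMap <- function(entries = list()) {
  entries <- lapply(entries, function(v) sort(unique(as.character(v))))
  new("DrugTargetMap", entries = entries)
}

#' @rdname catalogue-accessors
#' @export
setMethod("drugEntries", "DrugTargetMap", function(x, ...) x@entries)

#' @describeIn DrugTargetMap number of mapped targets.
#' @param x a `DrugTargetMap`.
#' @export
setMethod("length", "DrugTargetMap", function(x) length(x@entries))

setMethod("show", "DrugTargetMap", function(object) {
  n <- length(object@entries)
  tot <- sum(lengths(object@entries))
  cat("DrugTargetMap:", n, "targets,", tot, "compound associations\n")
})

#' Expression dataset
#'
#' A normalized (log-like scale) genes-by-samples expression matrix with
#' per-sample metadata, stored as a [SummarizedExperiment::SummarizedExperiment].
#' The single assay is named `"exprs"`; `colData` carries `sample_id`,
#' `dataset_id`, `hpv_status` (`neg`/`pos`/`unknown`) and an optional
#' `replicate_group` marking technical duplicates; `rowData` may carry a
#' `symbol` column mapping reporters to gene symbols prior to consolidation.
#' Missing expression values are rejected at construction.
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'exprs' is required")
  m <- SummarizedExperiment::assay(object, "exprs")
  if (any(!is.finite(m)))
    return("expression matrix contains missing or non-finite values")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "dataset_id", "hpv_status")
  miss <- setdiff(need, colnames(cd))
  if (length(miss) > 0)
    return(paste0("missing sample metadata column(s): ",
                  paste(miss, collapse = ", ")))
  if (!all(cd$hpv_status %in% .HPV_LEVELS))
    return("hpv_status must be one of neg/pos/unknown")
  key <- paste(cd$dataset_id, cd$sample_id)
  if (any(duplicated(key)))
    return("sample_id must be unique within dataset")
  if (is.null(rownames(object)) || any(duplicated(rownames(object))))
    return("row ids must be present and unique")
  TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, rows = reporters or genes (rownames
#'   required), columns = samples.
#' @param samples `data.frame` with one row per column of `values`; columns
#'   `sample_id`, `dataset_id`, `hpv_status`, and optionally
#'   `replicate_group` (samples sharing a group are technical duplicates).
#' @param reporterToSymbol optional named character vector mapping reporter
#'   ids (names) to gene symbols, used by [consolidateToSymbols()].
#' @return a validated [ExpressionDataset-class].
#' @examples
#' m <- matrix(rnorm(12), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' ed <- ExpressionDataset(m, data.frame(
#'   sample_id = paste0("s", 1:3), dataset_id = "demo",
#'   hpv_status = c("neg", "neg", "pos")))
#' @export
ExpressionDataset <- function(values, samples, reporterToSymbol = NULL) {
  values <- as.matrix(values)
  samples <- as.data.frame(samples)
  if (is.null(samples$replicate_group))
    samples$replicate_group <- NA_character_
  samples$replicate_group <- as.character(samples$replicate_group)
  samples$replicate_group[!is.na(samples$replicate_group) &
                            !nzchar(samples$replicate_group)] <- NA_character_
  if (nrow(samples) != ncol(values))
    stop("sample metadata rows (", nrow(samples),
         ") do not match expression columns (", ncol(values), ")")
  colnames(values) <- samples$sample_id
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(reporterToSymbol)) {
    rd$symbol <- unname(reporterToSymbol[rownames(values)])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = SimpleList(exprs = values),
    colData = DataFrame(samples, row.names = samples$sample_id),
    rowData = rd)
  new("ExpressionDataset", se)
}

#' Expression values of an ExpressionDataset
#'
#' @param x an `ExpressionDataset`.
#' @return `exprValues`: the numeric matrix; `sampleInfo`: the sample
#'   metadata as a plain `data.frame`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname exprValues
#' @export
sampleInfo <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "ExpressionDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ExpressionDataset:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  dataset(s):", paste(unique(cd$dataset_id), collapse = ", "), "\n")
  cat("  HPV status:",
      paste(names(table(cd$hpv_status)), table(cd$hpv_status),
            sep = "=", collapse = " "), "\n")
})

#' Expressed surfaceome of a dataset
#'
#' The set of catalogued cell-surface genes falling in the top quartile (Q4)
#' of whole-transcriptome relative expression within one dataset.
#'
#' @slot dataset_id dataset identifier.
#' @slot genes character vector of gene symbols.
#' @slot source_quartile the tier the set was drawn from (always `"Q4"` for
#'   an expressed surfaceome).
#' @export
setClass("ExpressedSurfaceome",
         slots = c(dataset_id = "character", genes = "character",
                   source_quartile = "character"),
         prototype = prototype(source_quartile = "Q4"))

setValidity("ExpressedSurfaceome", function(object) {
  if (length(object@dataset_id) != 1L) return("dataset_id must be length 1")
  if (any(duplicated(object@genes))) return("genes must be unique")
  if (!(object@source_quartile %in% .QUARTILES))
    return("source_quartile must be one of Q1-Q4")
  TRUE
})

#' @rdname catalogue-accessors
#' @export
setMethod("expressedGenes", "ExpressedSurfaceome", function(x, ...) x@genes)

#' @rdname catalogue-accessors
#' @export
setMethod("datasetID", "ExpressedSurfaceome", function(x, ...) x@dataset_id)

#' @describeIn ExpressedSurfaceome number of genes in the set.
#' @param x an `ExpressedSurfaceome`.
#' @export
setMethod("length", "ExpressedSurfaceome", function(x) length(x@genes))

setMethod("show", "ExpressedSurfaceome", function(object) {
  cat("ExpressedSurfaceome [", object@dataset_id, "]: ",
      length(object@genes), " genes (tier ", object@source_quartile, ")\n",
      sep = "")
})
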