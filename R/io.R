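#' @importFrom utils read.delim write.table head
NULL

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[v %in% c("false", "f", "no", "n", "0")] <- FALSE
  bad <- !is.na(v) & nzchar(v) & is.na(out)
  if (any(bad))
    stop("cannot interpret value(s) as logical: ",
         paste(unique(v[bad]), collapse = ", "))
  out
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), check.names = FALSE)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Read a surfaceome annotation catalogue from TSV
#'
#' Expected columns: `symbol`, `is_surfaceome`, and optionally `almen_main`,
#' `almen_sub`, `glycomineO_present`, `glycomineC_present`,
#' `noncyt_nxst_present`. Boolean columns accept `true/false`, `yes/no`,
#' `1/0` (case-insensitive); empty cells are absent (`NA`).
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect optional named character vector renaming file columns to
#'   the canonical schema: names are canonical column names, values the
#'   column names used in the file (e.g.
#'   `c(symbol = "gene", is_surfaceome = "surface")`).
#' @return a [SurfaceomeCatalogue-class].
#' @seealso [writeCatalogue()], [annotationJoin()]
#' @export
readCatalogue <- function(path, dialect = NULL) {
  df <- .read_tsv(path)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!(src %in% names(df)))
        stop("dialect column '", src, "' not found in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  for (col in c("symbol", "is_surfaceome")) {
    if (!(col %in% names(df)))
      stop("catalogue file is missing required column '", col, "'")
  }
  df$is_surfaceome <- .parse_logical(df$is_surfaceome)
  for (col in .MOTIF_COLS) {
    if (col %in% names(df)) df[[col]] <- .parse_logical(df[[col]])
  }
  dup <- unique(df$symbol[duplicated(trimws(df$symbol))])
  if (length(dup) > 0)
    stop("duplicated symbol(s) in catalogue: ", paste(dup, collapse = ", "))
  SurfaceomeCatalogue(df)
}

#' Write a surfaceome catalogue to TSV
#'
#' @param catalogue a [SurfaceomeCatalogue-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCatalogue <- function(catalogue, path) {
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  ann <- catalogueTable(catalogue)
  cols <- c("symbol", "is_surfaceome", "almen_main", "almen_sub", .MOTIF_COLS)
  out <- ann[, cols]
  for (col in c("is_surfaceome", .MOTIF_COLS))
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         ifelse(out[[col]], "true", "false"))
  .write_tsv(out, path)
  invisible(path)
}

#' Read a drug-target table from TSV
#'
#' One `(symbol, compound_id)` pair per row; compound sets per symbol are
#' deduplicated. An empty file yields an empty map with a warning.
#'
#' @param path path to a tab-separated file with columns `symbol` and
#'   `compound_id`.
#' @return a [DrugTargetMap-class].
#' @export
readDrugTable <- function(path) {
  df <- .read_tsv(path)
  for (col in c("symbol", "compound_id")) {
    if (!(col %in% names(df)))
      stop("drug table is missing required column '", col, "'")
  }
  df <- df[!is.na(df$symbol) & !is.na(df$compound_id), , drop = FALSE]
  if (nrow(df) == 0) {
    warning("drug table '", path, "' has no entries; returning an empty map")
    return(DrugTargetMap())
  }
  DrugTargetMap(split(as.character(df$compound_id),
                      trimws(as.character(df$symbol))))
}

#' Write a drug-target map to TSV
#'
#' @param drugs a [DrugTargetMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDrugTable <- function(drugs, path) {
  stopifnot(is(drugs, "DrugTargetMap"))
  e <- drugEntries(drugs)
  df <- data.frame(symbol = rep(names(e), lengths(e)),
                   compound_id = unlist(e, use.names = FALSE))
  if (nrow(df) == 0) df <- data.frame(symbol = character(),
                                      compound_id = character())
  .write_tsv(df, path)
  invisible(path)
}

#' Read an expression matrix plus sample metadata into an ExpressionDataset
#'
#' The expression file's first column is `symbol` or `reporter` (feature
#' ids); the remaining columns are one per sample and must match the
#' `sample_id` column of the metadata file. An optional `symbol` column in a
#' `reporter`-keyed file provides the reporter-to-symbol mapping used by
#' [consolidateToSymbols()].
#'
#' @param exprPath path to the expression TSV.
#' @param samplePath path to the sample metadata TSV with columns
#'   `sample_id`, `dataset_id`, `hpv_status`, `replicate_group`.
#' @return an [ExpressionDataset-class].
#' @export
readExpressionDataset <- function(exprPath, samplePath) {
  ex <- .read_tsv(exprPath)
  id_col <- intersect(c("symbol", "reporter"), names(ex))[1]
  if (is.na(id_col))
    stop("expression file must have a 'symbol' or 'reporter' first column")
  map <- NULL
  if (id_col == "reporter" && "symbol" %in% names(ex)) {
    map <- stats::setNames(as.character(ex$symbol), ex$reporter)
    ex$symbol <- NULL
  }
  ids <- as.character(ex[[id_col]])
  ex[[id_col]] <- NULL
  m <- as.matrix(ex)
  if (!is.numeric(m)) stop("expression columns must all be numeric")
  if (any(is.na(m))) stop("expression matrix contains missing values")
  rownames(m) <- ids
  samples <- .read_tsv(samplePath)
  miss <- setdiff(c("sample_id", "dataset_id", "hpv_status"), names(samples))
  if (length(miss) > 0)
    stop("sample metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(m)))
    stop("sample ids in metadata and expression matrix differ")
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  ExpressionDataset(m, samples, reporterToSymbol = map)
}

#' Write an ExpressionDataset to a pair of TSV files
#'
#' @param dataset an [ExpressionDataset-class].
#' @param exprPath,samplePath output paths for the expression matrix and the
#'   sample metadata.
#' @return `exprPath`, invisibly.
#' @export
writeExpressionDataset <- function(dataset, exprPath, samplePath) {
  stopifnot(is(dataset, "ExpressionDataset"))
  m <- exprValues(dataset)
  rd <- SummarizedExperiment::rowData(dataset)
  if ("symbol" %in% colnames(rd)) {
    ex <- data.frame(reporter = rownames(m), symbol = rd$symbol,
                     m, check.names = FALSE)
  } else {
    ex <- data.frame(symbol = rownames(m), m, check.names = FALSE)
  }
  .write_tsv(ex, exprPath)
  si <- sampleInfo(dataset)
  cols <- c("sample_id", "dataset_id", "hpv_status", "replicate_group")
  .write_tsv(si[, intersect(cols, names(si))], samplePath)
  invisible(exprPath)
}

#' Read a clinical table from TSV
#'
#' Columns: `patient_id  hpv_status  p16  histology  lvi  pT  pN  age_years
#' os_months  os_event`.
#'
#' @param path path to the clinical TSV.
#' @return a `data.frame` with typed columns.
#' @export
readClinicalTable <- function(path) {
  df <- .read_tsv(path)
  need <- c("patient_id", "hpv_status", "p16", "os_months", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$hpv_status %in% c("neg", "pos")))
    stop("clinical hpv_status must be 'neg' or 'pos'")
  if (!all(df$p16 %in% c("Negative", "Positive", "Unknown")))
    stop("p16 must be Negative/Positive/Unknown")
  if ("lvi" %in% names(df)) df$lvi <- .parse_logical(df$lvi)
  df$os_event <- .parse_logical(df$os_event)
  if (any(!is.finite(df$os_months) | df$os_months < 0))
    stop("os_months must be finite and non-negative")
  df
}

#' Read an immunohistochemistry scoring table from TSV
#'
#' Columns: `sample_id  marker  hpv_status  compartment  intensity
#' percent_positive`; a `percent_category` column is derived from
#' `percent_positive` when absent (1: <=25%, 2: 30-60%, 3: >=61%).
#'
#' @param path path to the IHC TSV.
#' @return a `data.frame`.
#' @export
readIHCTable <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "marker", "compartment", "percent_positive")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("IHC table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$compartment %in% c("membrane", "nuclear")))
    stop("compartment must be 'membrane' or 'nuclear'")
  if (any(df$percent_positive < 0 | df$percent_positive > 100))
    stop("percent_positive must lie in [0, 100]")
  if (!("percent_category" %in% names(df)))
    df$percent_category <- percentCategory(df$percent_positive)
  df
}

#' Ordinal percent-positivity category used in IHC scoring
#'
#' Maps percent of positively stained cells to the ordinal scale 1 (<= 25%),
#' 2 (30-60%), 3 (>= 61%); values falling between published bin edges are
#' assigned to the nearer bin.
#'
#' @param percent numeric vector in `[0, 100]`.
#' @return integer vector of categories 1-3.
#' @export
percentCategory <- function(percent) {
  stopifnot(all(percent >= 0 & percent <= 100))
  ifelse(percent <= 27.5, 1L, ifelse(percent <= 60.5, 2L, 3L))
}

#' Restrict a catalogue to a set of gene symbols
#'
#' Joins a query gene set to the catalogue by symbol (case-sensitive, after
#' whitespace trimming). Only symbols present in the catalogue are returned;
#' the count of unmatched symbols is attached as attribute `n_unmatched` and
#' reported via a message.
#'
#' @param symbols character vector of gene symbols.
#' @param catalogue a [SurfaceomeCatalogue-class].
#' @return the annotation `data.frame` restricted to matched symbols, with
#'   attribute `n_unmatched`.
#' @export
annotationJoin <- function(symbols, catalogue) {
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  symbols <- unique(trimws(as.character(symbols)))
  ann <- catalogueTable(catalogue)
  hit <- ann[ann$symbol %in% symbols, , drop = FALSE]
  n_unmatched <- length(symbols) - nrow(hit)
  if (n_unmatched > 0)
    message(n_unmatched, " symbol(s) not found in catalogue")
  rownames(hit) <- NULL
  attr(hit, "n_unmatched") <- n_unmatched
  hit
}
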