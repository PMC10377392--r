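#' @include AllClasses.R AllGenerics.R
NULL

.row_medians <- function(m) apply(m, 1L, stats::median)

#' Average technical duplicates into one column per replicate group
#'
#' Samples sharing a `replicate_group` are technical duplicates of the same
#' biological specimen; their expression columns are combined by the
#' arithmetic mean. Samples without a group are passed through unchanged.
#' Metadata of the first member (in column order) is retained for the
#' collapsed column, with `sample_id` set to the group label. Groups mixing
#' different HPV statuses are rejected.
#'
#' @param x an [ExpressionDataset-class].
#' @param ... unused.
#' @return an [ExpressionDataset-class] with one column per replicate group.
#' @examples
#' m <- matrix(c(4, 6, 1, 3), nrow = 1,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' ed <- ExpressionDataset(m, data.frame(
#'   sample_id = paste0("s", 1:4), dataset_id = "d",
#'   hpv_status = "neg", replicate_group = c("a", "a", "b", "b")))
#' exprValues(collapseReplicates(ed))  # a = 5, b = 2
#' @rdname collapseReplicates
#' @export
setMethod("collapseReplicates", "ExpressionDataset", function(x, ...) {
  si <- sampleInfo(x)
  grp <- si$replicate_group
  grp[is.na(grp)] <- si$sample_id[is.na(grp)]
  for (g in unique(grp)) {
    hs <- unique(si$hpv_status[grp == g])
    if (length(hs) > 1)
      stop("replicate group '", g, "' mixes HPV statuses: ",
           paste(hs, collapse = ", "))
  }
  if (!anyDuplicated(grp)) return(x)
  m <- exprValues(x)
  groups <- unique(grp)
  first <- match(groups, grp)
  collapsed <- vapply(groups, function(g) {
    cols <- which(grp == g)
    if (length(cols) == 1L) m[, cols] else rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  meta <- si[first, , drop = FALSE]
  meta$sample_id <- groups
  meta$replicate_group <- NA_character_
  rd <- SummarizedExperiment::rowData(x)
  map <- if ("symbol" %in% colnames(rd))
    stats::setNames(rd$symbol, rownames(x)) else NULL
  ExpressionDataset(collapsed, meta, reporterToSymbol = map)
})

#' Consolidate reporter-level rows to one row per gene symbol
#'
#' When several reporters measure the same gene, the reporter with the
#' highest median expression across samples is kept; ties are broken by the
#' lexicographically smallest reporter id. Reporters with no symbol mapping
#' are dropped (their count is reported via a message).
#'
#' @param x an [ExpressionDataset-class] whose `rowData` has a `symbol`
#'   column.
#' @param ... unused.
#' @return an [ExpressionDataset-class] with one row per symbol.
#' @rdname consolidateToSymbols
#' @export
setMethod("consolidateToSymbols", "ExpressionDataset", function(x, ...) {
  rd <- SummarizedExperiment::rowData(x)
  if (!("symbol" %in% colnames(rd)))
    stop("no reporter-to-symbol mapping present; supply 'reporterToSymbol' ",
         "when constructing the dataset")
  sym <- as.character(rd$symbol)
  keep <- !is.na(sym) & nzchar(sym)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " reporter(s) without a symbol dropped")
  m <- exprValues(x)[keep, , drop = FALSE]
  sym <- sym[keep]
  med <- .row_medians(m)
  # order: by symbol, then highest median first, ties by reporter id
  ord <- order(sym, -med, rownames(m), method = "radix")
  sel <- ord[!duplicated(sym[ord])]
  sel <- sel[order(sym[sel])]
  out <- m[sel, , drop = FALSE]
  rownames(out) <- sym[sel]
  ExpressionDataset(out, sampleInfo(x))
})

#' Per-sample ascending ranks of expression
#'
#' Ranks genes within each sample from lowest (rank 1) to highest
#' expression, assigning the average rank to ties.
#'
#' @param x an [ExpressionDataset-class] (consolidated: one row per gene) or
#'   a numeric matrix.
#' @param ... unused.
#' @return numeric matrix of ranks, same dimensions as the expression.
#' @rdname sampleRanks
#' @export
setMethod("sampleRanks", "ExpressionDataset", function(x, ...) {
  sampleRanks(exprValues(x))
})

#' @rdname sampleRanks
#' @export
setMethod("sampleRanks", "matrix", function(x, ...) {
  apply(x, 2L, rank, ties.method = "average")
})

#' Per-sample empirical-CDF quantiles of expression
#'
#' For gene g in sample s the quantile is the fraction of genes in s with
#' expression at or below that of g (the empirical CDF evaluated at the data
#' point); tied values share the same (upper) quantile. Values lie in
#' (0, 1] and every column attains 1 at its maximum.
#'
#' @param x an [ExpressionDataset-class] (consolidated) or numeric matrix.
#' @param ... unused.
#' @return numeric matrix of quantiles in (0, 1].
#' @examples
#' sampleQuantiles(matrix(c(1, 2, 3, 4), dimnames = list(1:4, "s")))
#' @rdname sampleQuantiles
#' @export
setMethod("sampleQuantiles", "ExpressionDataset", function(x, ...) {
  sampleQuantiles(exprValues(x))
})

#' @rdname sampleQuantiles
#' @export
setMethod("sampleQuantiles", "matrix", function(x, ...) {
  apply(x, 2L, function(col) rank(col, ties.method = "max") / length(col))
})

.quartile_of <- function(q) {
  cut(q, breaks = c(0, 0.25, 0.5, 0.75, 1), labels = .QUARTILES,
      right = TRUE)
}

#' Per-gene rank/quantile summaries and quartile tiers
#'
#' Computes, for every gene, the median across samples of its per-sample
#' rank and of its per-sample empirical-CDF quantile, then assigns the
#' quartile tier from the median quantile using the partition
#' (0, 0.25] -> Q1, (0.25, 0.5] -> Q2, (0.5, 0.75] -> Q3, (0.75, 1] -> Q4.
#' With an even number of samples the median is the midpoint of the two
#' central values. The result is deterministic and invariant to sample order
#' and to any strictly increasing per-sample transform of expression.
#'
#' @param x an [ExpressionDataset-class], consolidated to one row per gene.
#' @param ... unused.
#' @return a `data.frame` with columns `symbol`, `median_rank`,
#'   `median_quantile` and `quartile` (factor Q1-Q4).
#' @rdname summarizeGenes
#' @export
setMethod("summarizeGenes", "ExpressionDataset", function(x, ...) {
  m <- exprValues(x)
  if (ncol(m) < 1L) stop("at least one sample is required")
  mq <- .row_medians(sampleQuantiles(m))
  data.frame(symbol = rownames(m),
             median_rank = unname(.row_medians(sampleRanks(m))),
             median_quantile = unname(mq),
             quartile = .quartile_of(unname(mq)),
             row.names = NULL)
})
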