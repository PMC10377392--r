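#' @include AllClasses.R AllGenerics.R
NULL

#' Surfaceome genes of a dataset in a given expression tier
#'
#' Quartile tiers are computed over *all* genes of a dataset (the whole
#' transcriptome), and catalogued cell-surface genes are then binned into
#' them — so the four tiers generally hold unequal numbers of surfaceome
#' genes.
#'
#' @param summaries per-gene summaries from [summarizeGenes()], computed
#'   over all genes of the dataset (not the surfaceome subset).
#' @param catalogue a [SurfaceomeCatalogue-class].
#' @param tier one of `"Q1"`, `"Q2"`, `"Q3"`, `"Q4"`.
#' @return character vector of surfaceome gene symbols in the tier.
#' @export
quartileSubsets <- function(summaries, catalogue, tier = c("Q4", "Q1", "Q2", "Q3")) {
  tier <- match.arg(tier)
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  surf <- surfaceomeSymbols(catalogue)
  sort(summaries$symbol[summaries$quartile == tier &
                          summaries$symbol %in% surf])
}

#' Expressed surfaceome of a dataset
#'
#' The expressed surfaceome consists of the catalogued cell-surface genes
#' falling in the top quartile (Q4) of overall gene expression of the
#' dataset.
#'
#' @inheritParams quartileSubsets
#' @param dataset_id identifier recorded with the result.
#' @return an [ExpressedSurfaceome-class].
#' @export
expressedSurfaceome <- function(summaries, catalogue, dataset_id = "dataset") {
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  if (length(surfaceomeSymbols(catalogue)) == 0)
    warning("catalogue contains no surfaceome genes; result is empty")
  new("ExpressedSurfaceome", dataset_id = dataset_id,
      genes = quartileSubsets(summaries, catalogue, "Q4"),
      source_quartile = "Q4")
}

#' Intersect expressed surfaceomes across datasets
#'
#' Set intersection on gene symbols; symmetric, associative and idempotent.
#' Genes absent from one platform cannot enter that dataset's top tier, so
#' the intersection is restricted to genes covered by both.
#'
#' @param a,b [ExpressedSurfaceome-class] objects or character vectors of
#'   gene symbols.
#' @param ... unused.
#' @return sorted character vector of shared gene symbols.
#' @rdname intersectExpressed
#' @export
setMethod("intersectExpressed", signature("ExpressedSurfaceome", "ExpressedSurfaceome"),
          function(a, b, ...) sort(intersect(a@genes, b@genes)))

#' @rdname intersectExpressed
#' @export
setMethod("intersectExpressed", signature("character", "character"),
          function(a, b, ...) sort(intersect(a, b)))

#' Venn decomposition of several gene sets
#'
#' For k named sets, counts the genes falling in every non-empty region of
#' the Venn diagram (membership pattern), plus the global intersection and
#' union.
#'
#' @param sets named list (length >= 2) of character vectors.
#' @return a list with `regions` (a `data.frame` of membership pattern,
#'   member sets and count), `intersection` (character vector common to all
#'   sets) and `union_size`.
#' @examples
#' multiOverlap(list(a = c("x", "y"), b = c("y", "z")))$regions
#' @export
multiOverlap <- function(sets) {
  if (length(sets) < 2) stop("at least two sets are required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  all_genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(sets)))
  pattern <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(pattern)
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts), row.names = NULL)
  regions$sets <- vapply(regions$pattern, function(p) {
    paste(names(sets)[strsplit(p, "")[[1]] == "1"], collapse = "&")
  }, character(1))
  regions <- regions[order(-regions$count, regions$pattern), ]
  rownames(regions) <- NULL
  inter <- all_genes[rowSums(member) == length(sets)]
  list(regions = regions[, c("sets", "pattern", "count")],
       intersection = inter, union_size = length(all_genes))
}

#' Functional-class breakdown of a gene set
#'
#' Tallies a gene set by Almen main class or subclass. At the main level,
#' genes without an annotation (including genes missing from the catalogue)
#' are counted as `Unclassified`. Percentages are reported unrounded in
#' `percent` and rounded to integers in `percent_display`.
#'
#' @param genes character vector of gene symbols.
#' @param catalogue a [SurfaceomeCatalogue-class].
#' @param level `"main"` or `"sub"`.
#' @return a `data.frame` with columns `class`, `count`, `percent`,
#'   `percent_display`, ordered by decreasing count.
#' @export
classBreakdown <- function(genes, catalogue, level = c("main", "sub")) {
  level <- match.arg(level)
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  genes <- unique(genes)
  if (length(genes) == 0)
    return(data.frame(class = character(), count = integer(),
                      percent = numeric(), percent_display = integer()))
  ann <- catalogueTable(catalogue)
  col <- if (level == "main") "almen_main" else "almen_sub"
  cls <- ann[[col]][match(genes, ann$symbol)]
  cls[is.na(cls)] <- "Unclassified"
  tab <- sort(table(cls), decreasing = TRUE)
  out <- data.frame(class = names(tab), count = as.integer(tab),
                    row.names = NULL)
  out$percent <- 100 * out$count / length(genes)
  out$percent_display <- as.integer(round(out$percent))
  out
}
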