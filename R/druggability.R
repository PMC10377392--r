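#' Per-class druggability summary of a gene set
#'
#' Cross-references a gene set (typically an expressed surfaceome) with a
#' drug-target map and summarizes per Almen main class: number of targets,
#' total compound associations, mean compounds per target, number of targets
#' with at least one compound (a "target-drug hit"), and the percentage of
#' such targets. Multiple compounds on one target inflate the totals and
#' means only. Genes without a class annotation are counted as
#' `Unclassified`; drug-map symbols outside the gene set are ignored with a
#' warning. Classes are ordered by `n_targets_with_drug` descending.
#'
#' @param genes character vector of gene symbols.
#' @param catalogue a [SurfaceomeCatalogue-class].
#' @param drugs a [DrugTargetMap-class].
#' @return a `data.frame` with columns `class`, `n_targets`, `total_drugs`,
#'   `mean_drugs`, `n_targets_with_drug`, `percent_with_drug`, plus
#'   2-decimal display columns `mean_drugs_display` and
#'   `percent_with_drug_display`.
#' @export
druggabilitySummary <- function(genes, catalogue, drugs) {
  stopifnot(is(catalogue, "SurfaceomeCatalogue"), is(drugs, "DrugTargetMap"))
  genes <- unique(genes)
  entries <- drugEntries(drugs)
  unmatched <- setdiff(names(entries), genes)
  if (length(unmatched) > 0)
    warning(length(unmatched),
            " drug-map symbol(s) not in the gene set ignored")
  if (length(genes) == 0)
    return(data.frame(class = character(), n_targets = integer(),
                      total_drugs = integer(), mean_drugs = numeric(),
                      n_targets_with_drug = integer(),
                      percent_with_drug = numeric()))
  ann <- catalogueTable(catalogue)
  cls <- ann$almen_main[match(genes, ann$symbol)]
  cls[is.na(cls)] <- "Unclassified"
  n_comp <- vapply(genes, function(g) {
    v <- entries[[g]]
    if (is.null(v)) 0L else length(v)
  }, integer(1))
  agg <- lapply(split(n_comp, cls), function(v) {
    data.frame(n_targets = length(v), total_drugs = sum(v),
               n_targets_with_drug = sum(v > 0))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(class = names(agg), out, row.names = NULL)
  out$mean_drugs <- out$total_drugs / out$n_targets
  out$percent_with_drug <- 100 * out$n_targets_with_drug / out$n_targets
  out <- out[order(-out$n_targets_with_drug, out$class), , drop = FALSE]
  out$mean_drugs_display <- round(out$mean_drugs, 2)
  out$percent_with_drug_display <- round(out$percent_with_drug, 2)
  rownames(out) <- NULL
  out[, c("class", "n_targets", "total_drugs", "mean_drugs",
          "n_targets_with_drug", "percent_with_drug",
          "mean_drugs_display", "percent_with_drug_display")]
}
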