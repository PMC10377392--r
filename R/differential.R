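#' @importFrom stats t.test chisq.test sd
NULL

#' Two-sided Welch t-test
#'
#' Unequal-variance (Welch) two-sample t-test with Satterthwaite degrees of
#' freedom. Degenerate input in which both groups are constant and equal is
#' reported as no difference (t = 0, p = 1) with a warning so that screened
#' gene sets keep their full denominator.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a list with `t_statistic`, `df` and `p_value`.
#' @examples
#' welchTTest(c(1, 2, 3), c(11, 12, 13))
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least two observations")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("all values identical in both groups; reporting p = 1")
      return(list(t_statistic = 0, df = NA_real_, p_value = 1))
    }
    warning("zero variance in both groups with differing means")
    return(list(t_statistic = sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p_value = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Per-gene differential screen by HPV status
#'
#' Runs a two-sided Welch t-test per gene between HPV-negative and
#' HPV-positive samples of a dataset. P-values are unadjusted;
#' `significant` flags `p < alpha`. Genes absent from the matrix are skipped
#' (with a message); genes constant in both groups are reported with
#' p = 1 so that per-class denominators match the tested set.
#'
#' @param dataset an [ExpressionDataset-class] with >= 2 samples in each HPV
#'   group.
#' @param genes character vector of gene symbols to screen; defaults to all
#'   genes in the dataset.
#' @param alpha significance threshold for the `significant` flag
#'   (default 0.05, recorded as attribute `alpha`).
#' @return a `data.frame` with columns `symbol`, `mean_neg`, `mean_pos`,
#'   `t`, `p`, `significant`; attribute `alpha`.
#' @export
hpvScreen <- function(dataset, genes = NULL, alpha = 0.05) {
  stopifnot(is(dataset, "ExpressionDataset"))
  si <- sampleInfo(dataset)
  m <- exprValues(dataset)
  neg <- si$hpv_status == "neg"
  pos <- si$hpv_status == "pos"
  if (sum(neg) < 2 || sum(pos) < 2)
    stop("need at least two samples per HPV group (have ",
         sum(neg), " neg, ", sum(pos), " pos)")
  if (is.null(genes)) genes <- rownames(m)
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0)
    message(length(missing), " gene(s) absent from the matrix skipped")
  genes <- genes[genes %in% rownames(m)]
  res <- lapply(genes, function(g) {
    x <- m[g, neg]
    y <- m[g, pos]
    tt <- suppressWarnings(welchTTest(x, y))
    data.frame(symbol = g, mean_neg = mean(x), mean_pos = mean(y),
               t = tt$t_statistic, p = tt$p_value)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(symbol = character(), mean_neg = numeric(),
                      mean_pos = numeric(), t = numeric(), p = numeric())
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Per-class summary of differential screen hits
#'
#' For each Almen class (or subclass), reports how many screened genes were
#' significant out of how many were tested, mirroring a
#' "n different / n total (percent)" table.
#'
#' @param results output of [hpvScreen()].
#' @param catalogue a [SurfaceomeCatalogue-class].
#' @param level `"main"` or `"sub"`.
#' @return a `data.frame` with columns `class`, `n_different`, `n_total`,
#'   `percent`, `percent_display`.
#' @export
classDifferenceSummary <- function(results, catalogue, level = c("main", "sub")) {
  level <- match.arg(level)
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  ann <- catalogueTable(catalogue)
  col <- if (level == "main") "almen_main" else "almen_sub"
  cls <- ann[[col]][match(results$symbol, ann$symbol)]
  cls[is.na(cls)] <- "Unclassified"
  n_total <- table(cls)
  n_diff <- table(factor(cls, levels = names(n_total))[results$significant])
  out <- data.frame(class = names(n_total),
                    n_different = as.integer(n_diff),
                    n_total = as.integer(n_total), row.names = NULL)
  out$percent <- 100 * out$n_different / out$n_total
  out$percent_display <- as.integer(round(out$percent))
  out[order(-out$percent, out$class), , drop = FALSE]
}

#' Glycosylation-motif contingency test between expression tiers
#'
#' Compares the presence of a glycosylation motif between two tiers of
#' surfaceome expression (e.g. bottom vs top quartile) with Pearson's
#' chi-squared test on the 2x2 tier-by-presence table, *without* continuity
#' correction (df = 1, two-sided). The test is symmetric in tier order. A
#' zero marginal is rejected with a pointer to [fisherExact2x2()].
#'
#' @param tier_a,tier_b character vectors of gene symbols (both non-empty);
#'   every gene must carry the motif annotation in the catalogue.
#' @param catalogue a [SurfaceomeCatalogue-class].
#' @param motif `"O"`, `"C"` or `"noncyt_nxst"`.
#' @return a list with `table` (2x2 counts, tiers in rows), `statistic`,
#'   `df`, `p_value`, `method`.
#' @export
motifTierTest <- function(tier_a, tier_b, catalogue,
                          motif = c("O", "C", "noncyt_nxst")) {
  motif <- match.arg(motif)
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  if (length(tier_a) == 0 || length(tier_b) == 0)
    stop("both tiers must be non-empty")
  col <- switch(motif, O = "glycomineO_present", C = "glycomineC_present",
                noncyt_nxst = "noncyt_nxst_present")
  ann <- catalogueTable(catalogue)
  flag <- function(genes) {
    f <- ann[[col]][match(genes, ann$symbol)]
    if (any(is.na(f)))
      stop("gene(s) lacking ", col, " annotation: ",
           paste(head(genes[is.na(f)], 5L), collapse = ", "))
    f
  }
  fa <- flag(tier_a)
  fb <- flag(tier_b)
  tab <- rbind(tier_a = c(present = sum(fa), absent = sum(!fa)),
               tier_b = c(present = sum(fb), absent = sum(!fb)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the 2x2 table; use fisherExact2x2() instead")
  ht <- chisq.test(tab, correct = FALSE)
  list(table = tab, statistic = unname(ht$statistic),
       df = as.integer(unname(ht$parameter)), p_value = ht$p.value,
       method = "pearson_chisq_uncorrected")
}
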