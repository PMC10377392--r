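#' @importFrom stats fisher.test wilcox.test median quantile pchisq
#' @importFrom survival Surv survfit survdiff
NULL

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on fixed margins, the two-sided p-value sums the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one. A zero margin admits only the observed table, giving p = 1
#' with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts with a positive
#'   total.
#' @return a list with `table`, `p_value`, `method`.
#' @examples
#' fisherExact2x2(matrix(c(6, 1, 0, 10), nrow = 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            sum(table) > 0, all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: the observed table is the only one possible; p = 1")
    return(list(table = table, p_value = 1, method = "fisher_exact"))
  }
  ht <- fisher.test(table, alternative = "two.sided")
  list(table = table, p_value = ht$p.value, method = "fisher_exact")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value for small untied samples, normal approximation with tie
#' correction otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param x,y non-empty numeric vectors.
#' @return a list with `statistic` (Mann-Whitney W for `x`) and `p_value`.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Membrane vs nuclear comparison of IHC staining for one marker
#'
#' Compares percent of positively stained cells between the plasma-membrane
#' and nuclear compartments with an unpaired two-sided Wilcoxon rank-sum
#' test. A paired variant (by sample id) is available for sensitivity
#' analysis but is not the default.
#'
#' @param records IHC `data.frame` as from [readIHCTable()] or
#'   [simulateIHC()].
#' @param marker marker name to test; must be present in `records`.
#' @param paired if `TRUE`, a paired signed-rank test matching compartments
#'   within `sample_id`.
#' @return a list with `marker`, `n_membrane`, `n_nuclear`,
#'   `median_membrane`, `median_nuclear`, `statistic`, `p_value`, `paired`.
#' @export
ihcCompartmentCompare <- function(records, marker, paired = FALSE) {
  if (!(marker %in% records$marker))
    stop("marker '", marker, "' not present in the IHC records")
  rec <- records[records$marker == marker, , drop = FALSE]
  mem <- rec[rec$compartment == "membrane", , drop = FALSE]
  nuc <- rec[rec$compartment == "nuclear", , drop = FALSE]
  if (nrow(mem) < 2 || nrow(nuc) < 2)
    stop("need at least two records per compartment for marker '", marker, "'")
  if (paired) {
    common <- intersect(mem$sample_id, nuc$sample_id)
    xm <- mem$percent_positive[match(common, mem$sample_id)]
    xn <- nuc$percent_positive[match(common, nuc$sample_id)]
    ht <- suppressWarnings(wilcox.test(xm, xn, paired = TRUE))
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    res <- wilcoxonRankSum(mem$percent_positive, nuc$percent_positive)
  }
  list(marker = marker, n_membrane = nrow(mem), n_nuclear = nrow(nuc),
       median_membrane = median(mem$percent_positive),
       median_nuclear = median(nuc$percent_positive),
       statistic = res$statistic, p_value = res$p_value, paired = paired)
}

#' Split patients into high/low by the median expression value
#'
#' `high` means expression strictly above the median; ties at the median go
#' to `low`, so an even cohort of distinct values splits in half. A vector
#' with fewer than two distinct values cannot be split and is rejected.
#'
#' @param expression numeric vector of one gene's expression over patients.
#' @return factor with levels `low`, `high`, same length as `expression`.
#' @examples
#' dichotomizeByMedian(c(1, 2, 3, 4))
#' @export
dichotomizeByMedian <- function(expression) {
  if (length(expression) < 2)
    stop("need at least two patients to dichotomize")
  if (length(unique(expression)) < 2)
    stop("all expression values are identical; no median split possible")
  factor(ifelse(expression > median(expression), "high", "low"),
         levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank comparison between groups
#'
#' Fits the product-limit estimator of overall survival per group and
#' compares the groups with a two-sided log-rank test (chi-squared, 1 df for
#' two groups). The median OS of a group is the earliest time at which the
#' survival estimate drops to 0.5 or below; if the curve never crosses 0.5
#' the median is "not reached" and reported as `NA`.
#'
#' @param records clinical `data.frame` with columns `os_months` and
#'   `os_event` (`TRUE` = death observed).
#' @param groups factor or character vector of group labels, one per record;
#'   both groups must be non-empty.
#' @return a list with `fit` (the [survival::survfit] object), `summary`
#'   (per-group `data.frame`: `group`, `n`, `events`, `median_os`),
#'   `logrank_statistic`, `logrank_df`, `logrank_p`.
#' @export
kmLogrank <- function(records, groups) {
  stopifnot(nrow(records) == length(groups))
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("all groups must be non-empty")
  time <- records$os_months
  event <- as.integer(records$os_event)
  fit <- survfit(Surv(time, event) ~ groups)
  grp_names <- levels(groups)
  strat <- rep(grp_names, fit$strata)
  med <- vapply(grp_names, function(g) {
    s <- fit$surv[strat == g]
    t_g <- fit$time[strat == g]
    if (any(s <= 0.5)) min(t_g[s <= 0.5]) else NA_real_
  }, numeric(1))
  sdiff <- survdiff(Surv(time, event) ~ groups)
  df <- length(sdiff$n) - 1L
  p <- pchisq(sdiff$chisq, df = df, lower.tail = FALSE)
  n_by <- as.integer(table(groups))
  ev_by <- as.integer(tapply(event, groups, sum))
  list(fit = fit,
       summary = data.frame(group = grp_names, n = n_by, events = ev_by,
                            median_os = unname(med), row.names = NULL),
       logrank_statistic = unname(sdiff$chisq), logrank_df = df,
       logrank_p = p)
}

#' Median-split survival comparison for one gene
#'
#' Convenience wrapper: dichotomizes patients into high/low by the median of
#' one gene's expression and runs [kmLogrank()].
#'
#' @param records clinical `data.frame` with `patient_id`, `os_months`,
#'   `os_event`.
#' @param dataset an [ExpressionDataset-class] whose columns are the
#'   patients (matched by `patient_id`).
#' @param gene gene symbol present in the dataset.
#' @return as [kmLogrank()], plus `gene` and the `groups` factor.
#' @export
survivalByMedianSplit <- function(records, dataset, gene) {
  stopifnot(is(dataset, "ExpressionDataset"))
  m <- exprValues(dataset)
  if (!(gene %in% rownames(m)))
    stop("gene '", gene, "' not present in the expression dataset")
  idx <- match(records$patient_id, colnames(m))
  if (any(is.na(idx)))
    stop("patient(s) missing from the expression dataset: ",
         paste(records$patient_id[is.na(idx)], collapse = ", "))
  grp <- dichotomizeByMedian(m[gene, idx])
  res <- kmLogrank(records, grp)
  res$gene <- gene
  res$groups <- grp
  res
}

#' Clinicopathologic summary table with per-variable tests
#'
#' Summarizes a clinical cohort by HPV status: continuous variables as
#' median (IQR) with a two-sided Wilcoxon rank-sum p-value, categorical
#' variables as n (%) per level with a Fisher exact p-value (2 x k levels;
#' exact enumeration, falling back to Monte-Carlo simulation for tables too
#' large to enumerate, flagged in the `test` column).
#'
#' @param records clinical `data.frame`; must contain `hpv_status` with
#'   values `neg`/`pos`.
#' @param variables column names to summarize; defaults to every column
#'   except `patient_id`, `hpv_status`, `os_months` and `os_event`
#'   plus `age_years` if present.
#' @return a `data.frame` with one row per variable level: `variable`,
#'   `level`, `neg`, `pos` (formatted summaries), `p_value` (on the first
#'   row of each variable), `test`.
#' @export
cohortTable <- function(records, variables = NULL) {
  stopifnot(all(records$hpv_status %in% c("neg", "pos")))
  if (is.null(variables)) {
    variables <- setdiff(names(records),
                         c("patient_id", "hpv_status", "os_months", "os_event"))
  }
  is_neg <- records$hpv_status == "neg"
  rows <- list()
  for (v in variables) {
    x <- records[[v]]
    if (is.numeric(x)) {
      p <- if (length(unique(x)) == 1) 1 else
        suppressWarnings(wilcox.test(x[is_neg], x[!is_neg])$p.value)
      fmt <- function(z) sprintf("%.0f (%.0f, %.0f)", median(z),
                                 quantile(z, 0.25), quantile(z, 0.75))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "", neg = fmt(x[is_neg]), pos = fmt(x[!is_neg]),
        p_value = p, test = "wilcoxon_rank_sum")
    } else {
      x <- factor(x)
      tab <- table(x, factor(ifelse(is_neg, "neg", "pos"),
                             levels = c("neg", "pos")))
      test_name <- "fisher_exact"
      p <- tryCatch(fisher.test(tab)$p.value, error = function(e) {
        test_name <<- "fisher_exact_montecarlo"
        fisher.test(tab, simulate.p.value = TRUE, B = 100000)$p.value
      })
      fmt <- function(n, tot) {
        pct <- if (tot == 0) rep(0, length(n)) else 100 * n / tot
        sprintf("%d (%.0f%%)", n, pct)
      }
      lv <- rownames(tab)
      block <- data.frame(
        variable = v, level = lv,
        neg = fmt(tab[, "neg"], sum(is_neg)),
        pos = fmt(tab[, "pos"], sum(!is_neg)),
        p_value = c(p, rep(NA_real_, length(lv) - 1L)),
        test = test_name)
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
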