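# exhaustive hypergeometric enumeration for a 2x2 table with fixed margins
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("fisherExact2x2 matches exhaustive enumeration over fixed margins", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  set.seed(51)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact2x2(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-9)
  }

  # two-sided p >= one-sided p; both <= 1
  tab <- matrix(c(6, 1, 0, 10), 2, byrow = TRUE)
  two <- fisherExact2x2(tab)$p_value
  one <- fisher.test(tab, alternative = "less")$p.value
  expect_gte(two, min(one, fisher.test(tab, alternative = "greater")$p.value))
  expect_lte(two, 1)

  expect_warning(z <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(z$p_value, 1)
})

test_that("wilcoxonRankSum matches the exhaustive permutation distribution", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3, 5), c(1, 2, 3, 5))$p_value, 1)

  # maximal separation at n = 3 vs 3: two-sided exact p = 0.1
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(10, 20, 30))$p_value, 0.1)

  # random untied 5 vs 5 equals enumeration over all C(10,5) assignments
  set.seed(52)
  for (i in 1:5) {
    z <- sample(seq(0.1, 10, length.out = 10))  # untied
    x <- z[1:5]; y <- z[6:10]
    got <- wilcoxonRankSum(x, y)
    combos <- combn(10, 5)
    r <- rank(z)
    w_all <- apply(combos, 2, function(idx) sum(r[idx])) - 5 * 6 / 2
    w_obs <- sum(r[1:5]) - 5 * 6 / 2
    # two-sided exact p: doubled smaller tail (W symmetric about 12.5)
    p_or <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
    expect_equal(got$p_value, min(p_or, 1))
    expect_equal(got$statistic, w_obs)
  }
})

test_that("IHC membrane-vs-nuclear comparison detects planted separation", {
  rec <- data.frame(
    sample_id = rep(sprintf("s%d", 1:6), 2),
    marker = "CD147",
    compartment = rep(c("membrane", "nuclear"), each = 6),
    percent_positive = rep(c(90, 5), each = 6))
  r <- ihcCompartmentCompare(rec, "CD147")
  expect_lt(r$p_value, 0.01)
  expect_equal(r$median_membrane, 90)

  # identical compartment distributions -> p = 1
  rec2 <- rec
  rec2$percent_positive <- rep(c(50, 60, 70), 4)
  expect_equal(ihcCompartmentCompare(rec2, "CD147")$p_value, 1)

  expect_error(ihcCompartmentCompare(rec, "FGFR1"), "FGFR1")

  # planted membrane excess is detected in >90% of simulated cohorts
  set.seed(53)
  hits <- 0L
  for (i in 1:200) {
    sim <- data.frame(
      sample_id = rep(sprintf("s%d", 1:12), 2), marker = "M",
      compartment = rep(c("membrane", "nuclear"), each = 12),
      percent_positive = c(pmin(100, rnorm(12, 80, 15)),
                           pmax(0, rnorm(12, 30, 15))))
    if (ihcCompartmentCompare(sim, "M")$p_value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.9)
})

test_that("dichotomizeByMedian sends ties at the median to the low group", {
  expect_equal(as.character(dichotomizeByMedian(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomizeByMedian(c(1, 2, 3))),
               c("low", "low", "high"))
  expect_error(dichotomizeByMedian(rep(2, 5)), "identical")
  expect_error(dichotomizeByMedian(3), "at least two")

  set.seed(54)
  for (i in 1:10) {
    x <- rnorm(sample(4:30, 1))
    g <- dichotomizeByMedian(x)
    expect_identical(g == "high", x > median(x))
    expect_true(all(table(g) > 0))  # both groups non-empty, distinct values
  }
})

test_that("KM estimator and log-rank behave as the product-limit theory says", {
  # no censoring: KM equals the empirical survival function
  rec <- data.frame(os_months = c(3, 1, 4, 1, 5, 9, 2, 6),
                    os_event = TRUE)
  km <- kmLogrank(rec, rep(c("a", "b"), each = 4))
  sf <- summary(km$fit)
  times_a <- sort(rec$os_months[1:4])
  emp_a <- vapply(unique(times_a), function(t) mean(rec$os_months[1:4] > t),
                  numeric(1))
  in_a <- grepl("a$", as.character(sf$strata))
  expect_equal(sf$surv[in_a], emp_a)

  # hand-derived medians on a toy 4-patient group: S drops to 0.5 at t = 2
  toy <- data.frame(os_months = c(1, 2, 3, 4), os_event = TRUE)
  km2 <- kmLogrank(rbind(toy, toy), rep(c("x", "y"), each = 4))
  expect_equal(km2$summary$median_os, c(2, 2))  # S first reaches 0.5 at t = 2
  # identical event times in both groups: statistic 0, p = 1
  expect_equal(km2$logrank_statistic, 0)
  expect_equal(km2$logrank_p, 1)

  # label swap leaves the log-rank untouched
  set.seed(55)
  recs <- data.frame(os_months = rexp(20, 0.05),
                     os_event = runif(20) < 0.8)
  g <- rep(c("low", "high"), 10)
  swapped <- ifelse(g == "low", "high", "low")
  expect_equal(kmLogrank(recs, g)$logrank_statistic,
               kmLogrank(recs, swapped)$logrank_statistic)
  expect_equal(kmLogrank(recs, g)$logrank_p, kmLogrank(recs, swapped)$logrank_p)

  # group with zero events: median undefined, log-rank still computed
  cens <- data.frame(os_months = c(1, 2, 3, 4, 5, 6, 7, 8),
                     os_event = rep(c(TRUE, FALSE), each = 4))
  km3 <- kmLogrank(cens, rep(c("ev", "none"), each = 4))
  expect_true(is.na(km3$summary$median_os[km3$summary$group == "none"]))
  expect_true(is.finite(km3$logrank_p))

  expect_error(kmLogrank(toy, rep("x", 4)), "non-empty")
})

test_that("log-rank has power against a planted hazard ratio of 4", {
  # exponential survival, HR 4, n = 9 vs 9: rejection rate at 0.05 > 60%
  set.seed(56)
  rejections <- 0L
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    t_lo <- rexp(9, 0.02)
    t_hi <- rexp(9, 0.08)
    rec <- data.frame(os_months = c(t_lo, t_hi), os_event = TRUE)
    if (kmLogrank(rec, rep(c("lo", "hi"), each = 9))$logrank_p < 0.05)
      rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.6)
})

test_that("survivalByMedianSplit wires expression to the survival comparison", {
  set.seed(57)
  cfg <- small_sim_config(seed = 57)
  tum <- simulateTumors(cfg)
  res <- survivalByMedianSplit(tum$clinical, tum$dataset, markerGene(cfg))
  expect_setequal(res$summary$group, c("low", "high"))
  expect_equal(sum(res$summary$n), nrow(tum$clinical))
  expect_lte(res$logrank_p, 1)
  expect_error(survivalByMedianSplit(tum$clinical, tum$dataset, "NOPE"),
               "NOPE")
})

test_that("cohortTable summarizes a cohort with the right tests", {
  fx <- fixturePaperTables()$clinical
  ct <- cohortTable(fx$records)
  # categorical row counts per variable sum to 18
  for (v in c("p16", "histology")) {
    rows <- ct[ct$variable == v, ]
    n_from <- function(s) as.integer(sub(" .*", "", s))
    expect_equal(sum(n_from(rows$neg)) + sum(n_from(rows$pos)), 18L)
  }
  # p16 association (including the Unknown row) is highly significant
  expect_lt(ct$p_value[ct$variable == "p16"][1], 0.001)
  expect_equal(ct$test[ct$variable == "p16"][1], "fisher_exact")
  expect_equal(ct$test[ct$variable == "age_years"][1], "wilcoxon_rank_sum")

  # identical age values in every patient: p = 1
  rec <- fx$records
  rec$age_years <- 58
  expect_equal(cohortTable(rec, variables = "age_years")$p_value, 1)
})
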