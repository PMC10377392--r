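#' @importFrom stats rnorm rbinom rpois rexp runif setNames
NULL

#' Simulation configuration for synthetic pipeline inputs
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' emulate the study conditions the analysis assumes: a catalogue of 2886
#' cell-surface genes inside a 20,000-gene transcriptome with functional
#' class proportions of roughly 25% receptors, 18% transporters, 7% enzymes,
#' 16% miscellaneous and 34% unclassified; five HPV-negative cell lines
#' arrayed in duplicate; an 18-tumor cohort with 10 HPV-positive samples;
#' tier-dependent glycosylation-motif frequencies; per-class drug-hit rates
#' of about 23/22/21/6/1 percent; and exponential survival driven by one
#' marker gene.
#'
#' @param seed integer seed; every generator derives its own deterministic
#'   substream from it.
#' @param n_genes total genes in the simulated transcriptome.
#' @param n_surfaceome number of catalogued cell-surface genes.
#' @param class_proportions named probabilities over the Almen main classes
#'   (must sum to 1).
#' @param n_cell_lines number of cell lines (each arrayed in duplicate).
#' @param n_tumors,n_hpv_pos tumor cohort size and number of HPV-positive
#'   tumors.
#' @param planted_high_fraction fraction of surfaceome genes given a
#'   high-expression shift (the "planted" expressed surfaceome).
#' @param high_shift size of the planted shift in units of the
#'   between-gene baseline SD.
#' @param baseline_mean,baseline_sd mean and SD of per-gene baseline
#'   log-scale expression.
#' @param line_effect_sd SD of the per-cell-line biological effect shared by
#'   both technical duplicates.
#' @param replicate_noise_sd SD of duplicate-specific technical noise.
#' @param tumor_noise_sd per-tumor biological + technical noise SD.
#' @param hpv_effect_size HPV effect on affected genes, in units of
#'   `tumor_noise_sd` (the within-group SD).
#' @param hpv_effect_fraction fraction of surfaceome genes receiving an HPV
#'   effect (random sign).
#' @param motif_prob_high,motif_prob_low named per-motif presence
#'   probabilities (`O`, `C`, `noncyt_nxst`) for planted-high vs other
#'   surfaceome genes.
#' @param drug_rate named per-class probability that a target carries at
#'   least one compound.
#' @param compounds_per_hit mean compounds per drugged target (1 plus a
#'   Poisson count).
#' @param survival_baseline_hazard baseline hazard per month for the
#'   marker-low group.
#' @param survival_log_hr log hazard ratio of the marker-high group.
#' @param censor_rate expected fraction of censored observations in the
#'   marker-low group.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_genes = 20000L,
                             n_surfaceome = 2886L,
                             class_proportions = c(Receptors = 0.25,
                                                   Transporters = 0.18,
                                                   Enzymes = 0.07,
                                                   Miscellaneous = 0.16,
                                                   Unclassified = 0.34),
                             n_cell_lines = 5L,
                             n_tumors = 18L,
                             n_hpv_pos = 10L,
                             planted_high_fraction = 0.15,
                             high_shift = 2.5,
                             baseline_mean = 6,
                             baseline_sd = 2,
                             line_effect_sd = 0.3,
                             replicate_noise_sd = 0.3,
                             tumor_noise_sd = 1,
                             hpv_effect_size = 2,
                             hpv_effect_fraction = 0.1,
                             motif_prob_high = c(O = 0.22, C = 0.20,
                                                 noncyt_nxst = 0.97),
                             motif_prob_low = c(O = 0.10, C = 0.19,
                                                noncyt_nxst = 0.94),
                             drug_rate = c(Receptors = 0.234,
                                           Transporters = 0.225,
                                           Enzymes = 0.212,
                                           Miscellaneous = 0.0145,
                                           Unclassified = 0.063),
                             compounds_per_hit = 3,
                             survival_baseline_hazard = 0.02,
                             survival_log_hr = log(4),
                             censor_rate = 0.3) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_surfaceome = as.integer(n_surfaceome),
              class_proportions = class_proportions,
              n_cell_lines = as.integer(n_cell_lines),
              n_tumors = as.integer(n_tumors),
              n_hpv_pos = as.integer(n_hpv_pos),
              planted_high_fraction = planted_high_fraction,
              high_shift = high_shift, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, line_effect_sd = line_effect_sd,
              replicate_noise_sd = replicate_noise_sd,
              tumor_noise_sd = tumor_noise_sd,
              hpv_effect_size = hpv_effect_size,
              hpv_effect_fraction = hpv_effect_fraction,
              motif_prob_high = motif_prob_high,
              motif_prob_low = motif_prob_low,
              drug_rate = drug_rate, compounds_per_hit = compounds_per_hit,
              survival_baseline_hazard = survival_baseline_hazard,
              survival_log_hr = survival_log_hr, censor_rate = censor_rate)
  if (abs(sum(cfg$class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  probs <- c(cfg$planted_high_fraction, cfg$hpv_effect_fraction,
             cfg$motif_prob_high, cfg$motif_prob_low, cfg$drug_rate,
             cfg$censor_rate, cfg$class_proportions)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_hpv_pos > cfg$n_tumors)
    stop("n_hpv_pos cannot exceed n_tumors")
  if (cfg$n_surfaceome > cfg$n_genes)
    stop("n_surfaceome cannot exceed n_genes")
  class(cfg) <- "SimulationConfig"
  cfg
}

# deterministic per-generator substream; keeps derived seeds below 2^31
.substream <- function(config, k) {
  (abs(config$seed) %% 1000003L) * 1009L + k
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.gene_symbols <- function(n) sprintf("G%05d", seq_len(n))

#' Genes planted as highly expressed, and the survival marker gene
#'
#' The planted-high subset of the surfaceome (and the single marker gene
#' whose expression drives simulated survival) is a deterministic function
#' of the configuration seed, so every generator sees the same subset.
#'
#' @param config a [simulationConfig()].
#' @return character vector of planted gene symbols (`plantedHighGenes`);
#'   a single symbol (`markerGene`).
#' @export
plantedHighGenes <- function(config) {
  surf <- .surface_symbols(config)
  n <- round(config$planted_high_fraction * length(surf))
  sort(.with_seed(.substream(config, 9L), sample(surf, n)))
}

#' @rdname plantedHighGenes
#' @export
markerGene <- function(config) plantedHighGenes(config)[1L]

.surface_symbols <- function(config) {
  syms <- .gene_symbols(config$n_genes)
  sort(.with_seed(.substream(config, 8L),
                  sample(syms, config$n_surfaceome)))
}

#' Simulate a surfaceome annotation catalogue
#'
#' Draws `n_surfaceome` surface genes out of `n_genes`, assigns Almen main
#' classes from `class_proportions` (receptors and transporters also get
#' subclasses), and samples the three glycosylation-motif flags with
#' tier-dependent probabilities: planted-high genes use `motif_prob_high`,
#' all other surfaceome genes `motif_prob_low` — so a tier-vs-motif
#' enrichment is recoverable downstream.
#'
#' @param config a [simulationConfig()].
#' @return a [SurfaceomeCatalogue-class] covering all `n_genes` genes.
#' @export
simulateCatalogue <- function(config) {
  syms <- .gene_symbols(config$n_genes)
  surf_syms <- .surface_symbols(config)
  planted <- plantedHighGenes(config)
  .with_seed(.substream(config, 1L), {
    is_surf <- syms %in% surf_syms
    n_surf <- sum(is_surf)
    main <- rep(NA_character_, length(syms))
    main[is_surf] <- sample(names(config$class_proportions), n_surf,
                            replace = TRUE, prob = config$class_proportions)
    sub <- rep(NA_character_, length(syms))
    rec <- !is.na(main) & main == "Receptors"
    sub[rec] <- sample(c("GPCR", "IG", "SCAR", "Other receptors"),
                       sum(rec), replace = TRUE,
                       prob = c(0.14, 0.17, 0.10, 0.59))
    tra <- !is.na(main) & main == "Transporters"
    sub[tra] <- sample(c("SLC", "Channels", "Other transporters"),
                       sum(tra), replace = TRUE, prob = c(0.71, 0.08, 0.21))
    high <- syms %in% planted
    motif <- function(key) {
      p <- ifelse(high, config$motif_prob_high[[key]],
                  config$motif_prob_low[[key]])
      out <- rep(NA, length(syms))
      out[is_surf] <- runif(n_surf) < p[is_surf]
      out
    }
    SurfaceomeCatalogue(data.frame(
      symbol = syms, is_surfaceome = is_surf, almen_main = main,
      almen_sub = sub, glycomineO_present = motif("O"),
      glycomineC_present = motif("C"),
      noncyt_nxst_present = motif("noncyt_nxst")))
  })
}

.baseline_mu <- function(config, substream) {
  planted <- plantedHighGenes(config)
  syms <- .gene_symbols(config$n_genes)
  .with_seed(.substream(config, substream), {
    mu <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
    mu[syms %in% planted] <- mu[syms %in% planted] +
      config$high_shift * config$baseline_sd
    setNames(mu, syms)
  })
}

#' Simulate duplicated cell-line expression profiles
#'
#' Generates `2 * n_cell_lines` columns of log-scale expression: a per-gene
#' Gaussian baseline shared by all columns (planted-high surfaceome genes
#' shifted upward by `high_shift` baseline SDs), a per-line biological
#' effect shared by the two technical duplicates of a line, and
#' duplicate-specific noise. All cell lines are HPV-negative and duplicates
#' share a `replicate_group`.
#'
#' @param config a [simulationConfig()].
#' @return an [ExpressionDataset-class].
#' @export
simulateCellLines <- function(config) {
  mu <- .baseline_mu(config, 12L)
  .with_seed(.substream(config, 2L), {
    n_g <- config$n_genes
    cols <- list()
    meta <- list()
    for (l in seq_len(config$n_cell_lines)) {
      line_eff <- rnorm(n_g, 0, config$line_effect_sd)
      for (d in c("a", "b")) {
        id <- sprintf("CL%d_%s", l, d)
        cols[[id]] <- mu + line_eff + rnorm(n_g, 0, config$replicate_noise_sd)
        meta[[id]] <- data.frame(sample_id = id, dataset_id = "cell_lines",
                                 hpv_status = "neg",
                                 replicate_group = sprintf("CL%d", l))
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- names(mu)
    ExpressionDataset(m, do.call(rbind, meta))
  })
}

#' Simulate an HPV-mixed tumor cohort: expression plus clinical records
#'
#' Tumor expression uses an independent per-gene baseline (same planted-high
#' shift as the cell lines, emulating a different platform measuring the
#' same biology) plus per-tumor noise. A fraction `hpv_effect_fraction` of
#' surfaceome genes receives a shift of `hpv_effect_size` noise-SD units
#' (random sign) in HPV-positive tumors. Clinical records emulate a
#' clinicopathologic table: all HPV-positive tumors are p16-positive;
#' overall survival is exponential with the hazard of the marker-high group
#' (expression of [markerGene()] above its cohort median) multiplied by
#' `exp(survival_log_hr)`, under independent exponential censoring.
#'
#' @param config a [simulationConfig()].
#' @return a list with `dataset` (an [ExpressionDataset-class]) and
#'   `clinical` (a `data.frame` of patient records); attribute
#'   `hpv_effect_genes` on the result lists the genes given an HPV effect.
#' @export
simulateTumors <- function(config) {
  mu <- .baseline_mu(config, 13L)
  surf_syms <- .surface_symbols(config)
  marker <- markerGene(config)
  .with_seed(.substream(config, 3L), {
    n_t <- config$n_tumors
    n_pos <- config$n_hpv_pos
    hpv <- c(rep("neg", n_t - n_pos), rep("pos", n_pos))
    ids <- sprintf("T%02d", seq_len(n_t))
    n_eff <- round(config$hpv_effect_fraction * length(surf_syms))
    eff_genes <- sort(sample(surf_syms, n_eff))
    eff_sign <- sample(c(-1, 1), n_eff, replace = TRUE)
    shift <- setNames(rep(0, config$n_genes), names(mu))
    shift[eff_genes] <- eff_sign * config$hpv_effect_size * config$tumor_noise_sd
    m <- vapply(seq_len(n_t), function(i) {
      mu + (if (hpv[i] == "pos") shift else 0) +
        rnorm(config$n_genes, 0, config$tumor_noise_sd)
    }, numeric(config$n_genes))
    rownames(m) <- names(mu)
    colnames(m) <- ids
    dataset <- ExpressionDataset(
      m, data.frame(sample_id = ids, dataset_id = "tumors",
                    hpv_status = hpv,
                    replicate_group = NA_character_))
    # clinical covariates
    p16 <- ifelse(hpv == "pos", "Positive",
                  sample(c("Negative", "Positive", "Unknown"),
                         n_t, replace = TRUE, prob = c(0.75, 0.125, 0.125)))
    histology <- sample(c("Usual", "Basaloid", "Warty", "Verrucous",
                          "Mixed", "Other"), n_t, replace = TRUE,
                        prob = c(0.50, 0.11, 0.11, 0.11, 0.11, 0.06))
    lvi <- runif(n_t) < 0.7
    pT <- sample(1:3, n_t, replace = TRUE, prob = c(0.28, 0.28, 0.44))
    pN <- sample(0:3, n_t, replace = TRUE, prob = c(0.22, 0.06, 0.50, 0.22))
    age <- round(rnorm(n_t, 58, 9))
    # survival driven by the marker gene's median split
    high <- m[marker, ] > median(m[marker, ])
    hazard <- config$survival_baseline_hazard *
      exp(config$survival_log_hr * as.numeric(high))
    t_event <- rexp(n_t, rate = hazard)
    cens_hazard <- config$survival_baseline_hazard *
      config$censor_rate / max(1 - config$censor_rate, 1e-9)
    t_cens <- if (cens_hazard > 0) rexp(n_t, rate = cens_hazard)
              else rep(Inf, n_t)
    clinical <- data.frame(
      patient_id = ids, hpv_status = hpv, p16 = p16, histology = histology,
      lvi = lvi, pT = pT, pN = pN, age_years = age,
      os_months = round(pmin(t_event, t_cens), 2),
      os_event = t_event <= t_cens)
    out <- list(dataset = dataset, clinical = clinical)
    attr(out, "hpv_effect_genes") <- eff_genes
    attr(out, "marker") <- marker
    out
  })
}

#' Simulate a drug-target map over the surfaceome
#'
#' Each surfaceome gene becomes a target with probability
#' `drug_rate[class]`; hit targets receive `1 + Poisson(compounds_per_hit -
#' 1)` distinct compound identifiers.
#'
#' @param config a [simulationConfig()].
#' @param catalogue the matching [simulateCatalogue()] output.
#' @return a [DrugTargetMap-class].
#' @export
simulateDrugTable <- function(config, catalogue) {
  stopifnot(is(catalogue, "SurfaceomeCatalogue"))
  ann <- catalogueTable(catalogue)
  ann <- ann[ann$is_surfaceome, , drop = FALSE]
  .with_seed(.substream(config, 4L), {
    cls <- ann$almen_main
    cls[is.na(cls)] <- "Unclassified"
    rate <- config$drug_rate[cls]
    rate[is.na(rate)] <- 0
    hit <- runif(nrow(ann)) < rate
    if (!any(hit)) return(DrugTargetMap())
    n_comp <- 1L + rpois(sum(hit), max(config$compounds_per_hit - 1, 0))
    ids <- sprintf("D%06d", seq_len(sum(n_comp)))
    DrugTargetMap(split(ids, rep(ann$symbol[hit], n_comp)))
  })
}

#' Simulate an immunohistochemistry scoring table
#'
#' Twelve tumor samples (evenly split by HPV status) scored for three
#' surface markers in two subcellular compartments: membrane percent
#' positivity is drawn from a high-mean distribution, nuclear from a
#' low-mean one, with a marker-specific gap (smallest for FGFR1, which shows
#' the most membrane-vs-nuclear diversity). Intensity is strong (2-3) at
#' the membrane, weak (0-1) in the nucleus.
#'
#' @param config a [simulationConfig()].
#' @return a `data.frame` of 72 IHC records.
#' @export
simulateIHC <- function(config) {
  .with_seed(.substream(config, 5L), {
    samples <- sprintf("IHC%02d", 1:12)
    hpv <- rep(c("neg", "pos"), each = 6)
    mem_mean <- c(CD147 = 88, FGFR1 = 72, MCT1 = 85)
    nuc_mean <- c(CD147 = 12, FGFR1 = 38, MCT1 = 6)
    rows <- list()
    for (mk in names(mem_mean)) {
      for (comp in c("membrane", "nuclear")) {
        mean_pct <- if (comp == "membrane") mem_mean[[mk]] else nuc_mean[[mk]]
        pct <- pmin(100, pmax(0, rnorm(12, mean_pct, 10)))
        intensity <- if (comp == "membrane")
          sample(2:3, 12, replace = TRUE) else
          sample(0:1, 12, replace = TRUE)
        rows[[paste(mk, comp)]] <- data.frame(
          sample_id = samples, marker = mk, hpv_status = hpv,
          compartment = comp, intensity = intensity,
          percent_positive = round(pct, 1),
          percent_category = percentCategory(pct))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates every pipeline input under one configuration and writes them as
#' TSV files (`catalogue.tsv`, `cell_lines.tsv` + `cell_line_samples.tsv`,
#' `tumors.tsv` + `tumor_samples.tsv`, `drugs.tsv`, `clinical.tsv`,
#' `ihc.tsv`) plus a `config.json` echo. Identical configurations produce
#' identical files.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return named list of the file paths written, invisibly.
#' @export
simulateInputBundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  catalogue <- simulateCatalogue(config)
  writeCatalogue(catalogue, p("catalogue.tsv"))
  writeExpressionDataset(simulateCellLines(config),
                         p("cell_lines.tsv"), p("cell_line_samples.tsv"))
  tum <- simulateTumors(config)
  writeExpressionDataset(tum$dataset, p("tumors.tsv"), p("tumor_samples.tsv"))
  .write_tsv(tum$clinical, p("clinical.tsv"))
  writeDrugTable(simulateDrugTable(config, catalogue), p("drugs.tsv"))
  .write_tsv(simulateIHC(config), p("ihc.tsv"))
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(catalogue = p("catalogue.tsv"),
                 cell_lines = p("cell_lines.tsv"),
                 cell_line_samples = p("cell_line_samples.tsv"),
                 tumors = p("tumors.tsv"),
                 tumor_samples = p("tumor_samples.tsv"),
                 clinical = p("clinical.tsv"), drugs = p("drugs.tsv"),
                 ihc = p("ihc.tsv"), config = p("config.json")))
}
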