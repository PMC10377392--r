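#' Exact fixtures reproducing published summary-table marginals
#'
#' Deterministically constructs gene-level and patient-level tables whose
#' marginal counts equal, exactly, the figures of three published summary
#' tables, so the package's statistics can be recomputed from them:
#'
#' * `motif`: a catalogue of 736 surfaceome genes split into a bottom tier
#'   of 239 genes (24 O-motif, 45 C-motif, 224 N-X-S/T present) and a top
#'   tier of 497 genes (111 / 97 / 483) — feeding [motifTierTest()]
#'   reproduces the published motif-enrichment chi-squared p-values.
#' * `clinical`: an 18-patient cohort (8 HPV-negative, 10 HPV-positive)
#'   whose categorical columns (p16, histology, LVI, pT, pN) match the
#'   published clinicopathologic cross-tabs; the p16-by-HPV 2x2 (Unknown
#'   excluded) is `[[6,1],[0,10]]`. Ages and survival times are synthetic
#'   (ages match the published medians; per-patient survival was never
#'   published).
#' * `druggability`: a 519-gene set with per-class (targets, total drug
#'   associations, targets-with-drugs) of Receptors (115, 85, 27),
#'   Transporters (80, 56, 18), Unclassified (222, 25, 14), Enzymes
#'   (33, 12, 7), Miscellaneous (69, 1, 1) — feeding
#'   [druggabilitySummary()] reproduces the published mean-drugs-per-target
#'   and percent-with-drug columns.
#'
#' The construction uses no random numbers and is identical across runs.
#'
#' @return a list with elements `motif` (list: `catalogue`, `q1`, `q4`),
#'   `clinical` (list: `records`, `p16_table`), and `druggability` (list:
#'   `genes`, `catalogue`, `drugs`).
#' @export
fixturePaperTables <- function() {
  list(motif = .fixture_motif(), clinical = .fixture_clinical(),
       druggability = .fixture_druggability())
}

.fixture_motif <- function() {
  mk <- function(prefix, n, n_o, n_c, n_n) {
    data.frame(symbol = sprintf("%s%03d", prefix, seq_len(n)),
               is_surfaceome = TRUE, almen_main = NA_character_,
               almen_sub = NA_character_,
               glycomineO_present = seq_len(n) <= n_o,
               glycomineC_present = seq_len(n) <= n_c,
               noncyt_nxst_present = seq_len(n) <= n_n)
  }
  q1 <- mk("LOWQ", 239, 24, 45, 224)
  q4 <- mk("TOPQ", 497, 111, 97, 483)
  list(catalogue = SurfaceomeCatalogue(rbind(q1, q4)),
       q1 = q1$symbol, q4 = q4$symbol)
}

.fixture_clinical <- function() {
  rep_each <- function(values, counts) rep(values, times = counts)
  neg <- data.frame(
    patient_id = sprintf("PN%02d", 1:8), hpv_status = "neg",
    p16 = rep_each(c("Negative", "Positive", "Unknown"), c(6, 1, 1)),
    histology = rep_each(c("Usual", "Verrucous", "Other"), c(5, 2, 1)),
    lvi = rep_each(c(TRUE, FALSE), c(5, 3)),
    pT = rep_each(c(1, 2, 3), c(2, 4, 2)),
    pN = rep_each(c(0, 2, 3), c(3, 4, 1)),
    age_years = c(48, 50, 52, 57, 59, 66, 67, 70),
    os_months = c(12, 20, 28, 36, 44, 52, 60, 68),
    os_event = rep(c(TRUE, FALSE), 4))
  pos <- data.frame(
    patient_id = sprintf("PP%02d", 1:10), hpv_status = "pos",
    p16 = "Positive",
    histology = rep_each(c("Basaloid", "Mixed", "Usual", "Warty"),
                         c(2, 2, 4, 2)),
    lvi = rep_each(c(TRUE, FALSE), c(8, 2)),
    pT = rep_each(c(1, 2, 3), c(3, 1, 6)),
    pN = rep_each(c(0, 1, 2, 3), c(1, 1, 5, 3)),
    age_years = c(50, 52, 53, 55, 57, 59, 60, 63, 65, 68),
    os_months = c(10, 18, 26, 34, 42, 50, 58, 66, 74, 82),
    os_event = rep(c(TRUE, FALSE), 5))
  records <- rbind(neg, pos)
  known <- records[records$p16 != "Unknown", , drop = FALSE]
  p16_table <- table(factor(known$hpv_status, levels = c("neg", "pos")),
                     factor(known$p16, levels = c("Negative", "Positive")))
  p16_table <- matrix(as.integer(p16_table), nrow = 2,
                      dimnames = list(hpv = c("neg", "pos"),
                                      p16 = c("Negative", "Positive")))
  list(records = records, p16_table = p16_table)
}

.fixture_druggability <- function() {
  spec <- list(Receptors = c(prefix = "RCP", n = 115, total = 85, with = 27),
               Transporters = c(prefix = "TRN", n = 80, total = 56, with = 18),
               Unclassified = c(prefix = "UNC", n = 222, total = 25, with = 14),
               Enzymes = c(prefix = "ENZ", n = 33, total = 12, with = 7),
               Miscellaneous = c(prefix = "MSC", n = 69, total = 1, with = 1))
  ann <- list()
  entries <- list()
  drug_i <- 0L
  for (cls in names(spec)) {
    s <- spec[[cls]]
    n <- as.integer(s[["n"]])
    total <- as.integer(s[["total"]])
    n_with <- as.integer(s[["with"]])
    syms <- sprintf("%s%03d", s[["prefix"]], seq_len(n))
    ann[[cls]] <- data.frame(
      symbol = syms, is_surfaceome = TRUE,
      almen_main = if (cls == "Unclassified") NA_character_ else cls,
      almen_sub = NA_character_, glycomineO_present = FALSE,
      glycomineC_present = FALSE, noncyt_nxst_present = TRUE)
    # first drugged target absorbs the surplus so totals match exactly
    n_per <- c(total - (n_with - 1L), rep(1L, n_with - 1L))
    for (i in seq_len(n_with)) {
      ids <- sprintf("DB%05d", drug_i + seq_len(n_per[i]))
      drug_i <- drug_i + n_per[i]
      entries[[syms[i]]] <- ids
    }
  }
  ann <- do.call(rbind, ann)
  rownames(ann) <- NULL
  list(genes = ann$symbol, catalogue = SurfaceomeCatalogue(ann),
       drugs = DrugTargetMap(entries))
}
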