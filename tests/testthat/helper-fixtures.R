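# shared in-code fixtures: tiny catalogues and expression sets

tiny_catalogue <- function() {
  SurfaceomeCatalogue(data.frame(
    symbol = c("BSG", "FGFR1", "SLC16A1", "MRC1", "ACTB", "GAPDH"),
    is_surfaceome = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    almen_main = c("Unclassified", "Receptors", "Transporters",
                   "Receptors", NA, NA),
    almen_sub = c(NA, "Other receptors", "SLC", "SCAR", NA, NA),
    glycomineO_present = c(TRUE, FALSE, TRUE, FALSE, NA, NA),
    glycomineC_present = c(FALSE, FALSE, FALSE, TRUE, NA, NA),
    noncyt_nxst_present = c(TRUE, TRUE, TRUE, TRUE, NA, NA)))
}

# 8 genes x 2 samples with hand-known quartiles; columns agree in order so
# median quantiles equal the per-sample quantiles
eight_gene_dataset <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5),
              ncol = 2,
              dimnames = list(c("ACTB", "BSG", "GAPDH", "MRC1", "SLC16A1",
                                "TUBB", "FGFR1", "EEF2"),
                              c("s1", "s2")))
  ExpressionDataset(m, data.frame(sample_id = c("s1", "s2"),
                                  dataset_id = "demo", hpv_status = "neg"))
}

# catalogue for the 8-gene dataset: 2 surfaceome genes, FGFR1 in Q4
eight_gene_catalogue <- function() {
  SurfaceomeCatalogue(data.frame(
    symbol = c("BSG", "FGFR1"),
    is_surfaceome = TRUE,
    almen_main = c("Unclassified", "Receptors"),
    glycomineO_present = c(TRUE, FALSE),
    glycomineC_present = FALSE,
    noncyt_nxst_present = TRUE))
}

random_dataset <- function(n_genes, n_samples, seed = 1, hpv = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (is.null(hpv)) hpv <- rep("neg", n_samples)
  ExpressionDataset(m, data.frame(sample_id = colnames(m),
                                  dataset_id = "rand", hpv_status = hpv))
}

small_sim_config <- function(seed = 1, ...) {
  simulationConfig(seed = seed, n_genes = 2000, n_surfaceome = 400, ...)
}
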