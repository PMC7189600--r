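# Small in-code fixtures shared across the test files.

four_donor_samples <- function() {
  tibble::tibble(
    sample = c("D1_R", "D2_R", "D3_R", "D4_R", "D1_P", "D2_P", "D3_P", "D4_P"),
    donor = rep(paste0("D", 1:4), 2),
    condition = rep(c("resting", "primed"), each = 4)
  )
}

tiny_factor_panel <- function(conc = NULL, threshold = 4) {
  samples <- four_donor_samples()
  if (is.null(conc)) {
    conc <- matrix(c(100, 110, 90, 105, 300, 320, 290, 310,
                     50, 55, 45, 52, 48, 51, 47, 50,
                     2, 3, 5, 1, 6, 7, 8, 9),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("FAC1", "FAC2", "FAC3"), samples$sample))
  }
  factor_panel(conc, samples, assay_threshold = threshold,
               dilution_factor = 2, medium_volume = 5, cell_count = 1e6)
}

# Two-sample (one per condition) Crt table builder; mirnas on panel A unless
# listed in `panel_b`.
tiny_crt_table <- function(crt, panel_b = character(),
                           spike_a = c(15, 15), spike_b = c(16, 16)) {
  samples <- tibble::tibble(sample = c("S_R", "S_P"), donor = c("D1", "D1"),
                            condition = c("resting", "primed"))
  crt <- as.matrix(crt)
  colnames(crt) <- samples$sample
  panel_of <- stats::setNames(
    ifelse(rownames(crt) %in% panel_b, "B", "A"), rownames(crt))
  spike <- matrix(c(spike_a, spike_b), nrow = 2,
                  dimnames = list(samples$sample, c("A", "B")))
  crt_table(crt, samples, panel_of, spike)
}

# Minimal expression table with a single resting sample carrying the given
# per-miRNA relative expressions (used for selection-rule properties).
single_sample_expr <- function(rel_expr) {
  n <- length(rel_expr)
  ids <- sprintf("m%04d", seq_len(n))
  mat <- matrix(rel_expr, ncol = 1, dimnames = list(ids, "S1"))
  structure(list(
    delta_crt = -log2(mat), rel_expr = mat,
    samples = tibble::tibble(sample = "S1", donor = "D1", condition = "resting"),
    global_mean = 0, never_amplified = character()
  ), class = "expression_table")
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "secretomix", mustWork = TRUE)
}
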