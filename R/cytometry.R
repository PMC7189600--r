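# Flow-cytometry validation readouts: background-subtracted MFI fold
# changes, the CD86/CD163 polarization ratio, and positivity ratios for
# inflammation markers. Inputs are pre-summarized per-condition tables
# (median fluorescence intensity and/or % positive), never event-level data.

#' Background-subtracted MFI fold versus a control condition
#'
#' `fold = (mfi - unstained_mfi) / (control_mfi - control_unstained)`. The
#' control condition's own fold is 1 by construction, and the fold is
#' invariant to a common multiplicative gain applied to all MFIs of a marker.
#' A negative net sample MFI (staining below background) is clamped to a fold
#' of 0 with a warning.
#'
#' @param mfi,unstained_mfi sample median fluorescence intensity and its
#'   unstained control, arbitrary units (vectorized).
#' @param control_mfi,control_unstained the same for the reference condition.
#' @return fold change versus control.
#' @export
mfi_fold <- function(mfi, unstained_mfi, control_mfi, control_unstained) {
  net_ctrl <- control_mfi - control_unstained
  if (any(net_ctrl <= 0))
    stop("non-positive net control MFI", call. = FALSE)
  net <- mfi - unstained_mfi
  if (any(net < 0, na.rm = TRUE)) {
    warning("negative net MFI clamped to fold 0", call. = FALSE)
    net[net < 0] <- 0
  }
  net / net_ctrl
}

#' Macrophage polarization ratio
#'
#' Ratio of the CD86 (M1 marker) fold to the CD163 (M2 marker) fold, both
#' relative to the unstimulated control; the control condition maps to 1 by
#' construction, and values above 1 indicate M1 polarization.
#'
#' @param cd86_fold,cd163_fold background-subtracted MFI folds vs control.
#' @return polarization ratio.
#' @export
polarization_ratio <- function(cd86_fold, cd163_fold) {
  if (any(cd163_fold == 0)) stop("zero CD163 fold", call. = FALSE)
  if (any(cd86_fold < 0 | cd163_fold < 0))
    stop("folds must be positive", call. = FALSE)
  cd86_fold / cd163_fold
}

#' Positivity ratio of % positive cells
#'
#' Ratio of the treated condition's percentage of marker-positive cells to a
#' reference condition's. With donor-level vectors the ratio is computed per
#' donor and summarized as mean +/- SD (the per-sample ratio convention);
#' scalars give a single ratio of condition summaries.
#'
#' @param pct_treated,pct_reference percentages of positive cells, in
#'   \[0, 100\] (vectorized per donor).
#' @return list with `ratios`, `mean`, `sd`, and `convention` (`"per_donor"`
#'   or `"of_summaries"`).
#' @export
positivity_ratio <- function(pct_treated, pct_reference) {
  stopifnot(all(pct_treated >= 0 & pct_treated <= 100),
            all(pct_reference >= 0 & pct_reference <= 100))
  if (any(pct_reference == 0)) stop("zero reference percentage", call. = FALSE)
  ratios <- pct_treated / pct_reference
  list(ratios = ratios, mean = mean(ratios),
       sd = if (length(ratios) > 1) stats::sd(ratios) else NA_real_,
       convention = if (length(ratios) > 1) "per_donor" else "of_summaries")
}

#' Per-donor MFI folds for every condition of a flow readout table
#'
#' @param readouts tibble with columns `condition`, `marker`, `donor`, `mfi`,
#'   `unstained_mfi` (and optionally `pct_positive`).
#' @param control condition label used as reference (fold 1).
#' @return tibble: condition, marker, donor, fold.
#' @export
mfi_fold_table <- function(readouts, control) {
  stopifnot(control %in% readouts$condition)
  ctrl <- dplyr::filter(readouts, .data$condition == control) |>
    dplyr::select("marker", "donor", ctrl_mfi = "mfi",
                  ctrl_unstained = "unstained_mfi")
  dplyr::inner_join(readouts, ctrl, by = c("marker", "donor")) |>
    dplyr::mutate(fold = mfi_fold(.data$mfi, .data$unstained_mfi,
                                  .data$ctrl_mfi, .data$ctrl_unstained)) |>
    dplyr::select("condition", "marker", "donor", "fold")
}
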