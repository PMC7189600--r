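# ELISA layer: concentrations (pg/ml) -> secreted amount per million cells,
# all-samples detection rule, abundance tiers, inter-donor concordance.

TIER_LEVELS <- c("gt100ng", "10to100ng", "1to10ng", "lt1ng")

#' Secreted amount per million cells
#'
#' Converts an assayed concentration to the amount secreted per million cells
#' over the conditioning window: `conc * dilution * volume * 1e6 / cells`
#' (pg per 10^6 cells). Linear in concentration and volume, inverse in cell
#' count.
#'
#' @param conc concentration in the assayed (diluted) supernatant, pg/ml.
#' @param dilution unitless dilution factor applied before assay (>= 1).
#' @param volume conditioned-medium volume, ml.
#' @param cells cell count at harvest.
#' @return amount in pg per 10^6 cells; `NA` propagates.
#' @export
per_cell_amount <- function(conc, dilution = 1, volume, cells) {
  if (any(volume <= 0)) stop("volume must be positive", call. = FALSE)
  if (any(cells <= 0)) stop("cells must be positive", call. = FALSE)
  if (any(dilution < 1)) stop("dilution must be >= 1", call. = FALSE)
  conc * dilution * volume * 1e6 / cells
}

#' All-samples detection rule per condition
#'
#' An analyte counts as detected in a condition only when its concentration is
#' strictly above the per-analyte assay threshold in every sample of that
#' condition; missing concentrations fail the rule.
#'
#' @param panel a [factor_panel()].
#' @return list with character vectors `resting`, `primed`, and their `union`.
#' @export
detection_filter <- function(panel) {
  sets <- lapply(CONDITIONS, function(cond) {
    idx <- panel$samples$condition == cond
    if (!any(idx))
      stop(sprintf("no samples in condition '%s'", cond), call. = FALSE)
    sub <- panel$conc[, idx, drop = FALSE]
    above <- sweep(sub, 1, panel$assay_threshold, ">")
    above[is.na(above)] <- FALSE
    rownames(sub)[rowSums(above) == ncol(sub)]
  })
  names(sets) <- CONDITIONS
  c(sets, list(union = union(sets$resting, sets$primed)))
}

#' Map a mean amount to its abundance tier
#'
#' Tiers follow the reporting convention `> 100 ng`, `(10, 100]`, `(1, 10]`,
#' `<= 1` ng per 10^6 cells (upper-inclusive boundaries).
#'
#' @param mean_ng mean amount, ng per 10^6 cells (vectorized).
#' @return factor with levels `gt100ng`, `10to100ng`, `1to10ng`, `lt1ng`.
#' @export
assign_tier <- function(mean_ng) {
  cut(mean_ng, breaks = c(-Inf, 1, 10, 100, Inf),
      labels = rev(TIER_LEVELS), right = TRUE) |>
    factor(levels = TIER_LEVELS)
}

#' Compute per-cell secreted amounts with detection flags and tiers
#'
#' Applies [per_cell_amount()] to the whole panel and summarizes each analyte
#' per condition: detection under the all-samples rule, mean +/- SD amount in
#' ng per 10^6 cells across the condition's donors, and abundance tier
#' (assigned only to detected analytes).
#'
#' @param panel a [factor_panel()].
#' @return object of class `factor_amounts`: list with `amounts` (pg per 10^6
#'   cells, analyte x sample matrix), `samples`, `detected` (from
#'   [detection_filter()]), and `summary` (tidy tibble: analyte, condition,
#'   detected, mean_ng, sd_ng, tier).
#' @export
factor_amounts <- function(panel) {
  amounts <- per_cell_amount(panel$conc,
                             dilution = panel$dilution_factor,
                             volume = panel$medium_volume,
                             cells = rep(panel$cell_count, each = nrow(panel$conc)))
  detected <- detection_filter(panel)
  summ <- dplyr::bind_rows(lapply(CONDITIONS, function(cond) {
    idx <- panel$samples$condition == cond
    sub_ng <- amounts[, idx, drop = FALSE] / 1000
    tibble::tibble(
      analyte = rownames(amounts),
      condition = cond,
      detected = rownames(amounts) %in% detected[[cond]],
      mean_ng = rowMeans(sub_ng, na.rm = TRUE),
      sd_ng = apply(sub_ng, 1, stats::sd, na.rm = TRUE)
    )
  }))
  summ$tier <- assign_tier(summ$mean_ng)
  summ$tier[!summ$detected] <- NA
  structure(list(amounts = amounts, samples = panel$samples,
                 detected = detected, summary = summ),
            class = "factor_amounts")
}

#' @export
print.factor_amounts <- function(x, ...) {
  cat(sprintf("<factor_amounts> %d analytes; detected: %d resting, %d primed\n",
              nrow(x$amounts), length(x$detected$resting), length(x$detected$primed)))
  invisible(x)
}

#' Abundance tier map for one condition
#'
#' @param fa a [factor_amounts()] object.
#' @param condition `"resting"` or `"primed"`.
#' @return tibble (analyte, mean_ng, tier) restricted to analytes detected in
#'   the condition; the tiers partition that detected set.
#' @export
abundance_tiers <- function(fa, condition = c("resting", "primed")) {
  condition <- match.arg(condition)
  dplyr::filter(fa$summary, .data$condition == .env$condition, .data$detected) |>
    dplyr::select("analyte", "mean_ng", "tier")
}

#' Mean pairwise inter-donor correlation
#'
#' Pearson correlation of per-cell amounts between every unordered pair of
#' samples in a condition, restricted to the union detected set; missing
#' values are excluded pairwise. Pairs where either vector is constant have
#' no defined correlation and are skipped with a warning.
#'
#' @param fa a [factor_amounts()] object.
#' @param condition `"resting"`, `"primed"`, or `"all"` for every sample.
#' @return list with `mean`, `sd`, and the tibble `pairs` (sample_1,
#'   sample_2, r).
#' @export
mean_pairwise_correlation <- function(fa, condition = c("resting", "primed", "all")) {
  condition <- match.arg(condition)
  idx <- if (condition == "all") rep(TRUE, nrow(fa$samples))
         else fa$samples$condition == condition
  ids <- fa$samples$sample[idx]
  if (length(ids) < 2)
    stop("need at least two samples for pairwise correlation", call. = FALSE)
  mat <- fa$amounts[fa$detected$union, ids, drop = FALSE]
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    xy <- mat[, p]
    ok <- stats::complete.cases(xy)
    r <- if (sum(ok) < 3 || stats::sd(xy[ok, 1]) == 0 || stats::sd(xy[ok, 2]) == 0) {
      warning(sprintf("correlation undefined for pair %s-%s; skipped",
                      p[1], p[2]), call. = FALSE)
      NA_real_
    } else {
      stats::cor(xy[ok, 1], xy[ok, 2])
    }
    tibble::tibble(sample_1 = p[1], sample_2 = p[2], r = r)
  })
  pairs_df <- dplyr::bind_rows(rows)
  list(mean = mean(pairs_df$r, na.rm = TRUE),
       sd = stats::sd(pairs_df$r, na.rm = TRUE),
       pairs = pairs_df)
}
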