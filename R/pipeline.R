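# One-call orchestration of the full analysis on synthetic or real inputs:
# ELISA quantification, miRNA normalization and weighting, priming
# contrasts, and flow readouts, with tidy CSV export.

#' Run the full secretome analysis end to end
#'
#' Generates the three synthetic data layers from one configuration (or
#' accepts pre-built inputs), then runs every stage: per-cell amounts,
#' detection, tiers and inter-donor correlation for the ELISA layer; spike-in
#' equalization, censoring, global-mean normalization, detected sets,
#' first-quartile selection, category genetic weights and balance for the
#' miRNA layer; priming contrasts for both layers; MFI folds, polarization
#' ratios and positivity ratios for the flow layer. With `outdir` set, tidy
#' long-format CSVs are written alongside the returned objects.
#'
#' @param config a [synthetic_config()].
#' @param outdir optional directory for tidy CSV outputs.
#' @param elisa,crt,flow optional pre-built inputs (as returned by the
#'   generators) overriding simulation of that layer.
#' @return list with elements `elisa` (amounts, tiers, correlation,
#'   contrast), `mirna` (expression, detected, quartile, weights, balance,
#'   contrast), `flow` (folds, polarization, positivity), and the ground
#'   truths used.
#' @export
run_secretome_pipeline <- function(config = synthetic_config(), outdir = NULL,
                                   elisa = NULL, crt = NULL, flow = NULL) {
  elisa <- elisa %||% generate_elisa_panel(config)
  crt <- crt %||% generate_crt_table(config)
  flow <- flow %||% generate_flow_readouts(config)

  # --- ELISA layer
  fa <- factor_amounts(elisa$panel)
  tiers <- dplyr::bind_rows(
    dplyr::mutate(abundance_tiers(fa, "resting"), condition = "resting"),
    dplyr::mutate(abundance_tiers(fa, "primed"), condition = "primed")
  )
  corr <- lapply(c(resting = "resting", primed = "primed"),
                 function(cond) suppressWarnings(mean_pairwise_correlation(fa, cond)))
  elisa_contrast <- priming_contrast(fa$amounts, fa$samples, fa$detected)

  # --- miRNA layer
  expr <- crt$table |>
    spike_in_equalize() |>
    censor_unamplified(limit = config$crt_limit) |>
    global_mean_normalize()
  det <- detected_sets(expr)
  quartile <- lapply(c(resting = "resting", primed = "primed"),
                     function(cond) first_quartile_select(expr, cond))
  weights <- list()
  balance <- NULL
  if (length(crt$categories) >= 2) {
    nms <- names(crt$categories)[1:2]
    weights <- lapply(c(resting = "resting", primed = "primed"), function(cond) {
      lapply(crt$categories, genetic_weight, expr = expr, condition = cond)
    })
    balance <- category_balance(weights$resting[[nms[1]]], weights$resting[[nms[2]]],
                                weights$primed[[nms[1]]], weights$primed[[nms[2]]])
  }
  mirna_contrast <- priming_contrast(expr$rel_expr, expr$samples, det)

  # --- flow layer
  folds <- mfi_fold_table(flow$macrophage, control = "CTRL")
  fold_wide <- tidyr::pivot_wider(folds, names_from = "marker", values_from = "fold")
  polar <- dplyr::mutate(fold_wide,
                         polarization = polarization_ratio(.data$CD86, .data$CD163))
  polar_mean <- dplyr::summarise(dplyr::group_by(polar, .data$condition),
                                 cd86 = mean(.data$CD86), cd163 = mean(.data$CD163),
                                 polarization = mean(.data$polarization),
                                 .groups = "drop")
  cho <- flow$chondrocyte
  ref <- dplyr::filter(cho, .data$condition == "INFLAMED")
  positivity <- dplyr::bind_rows(lapply(
    setdiff(unique(cho$condition), c("CTRL", "INFLAMED")), function(cond) {
      tr <- dplyr::filter(cho, .data$condition == cond)
      pr <- positivity_ratio(tr$pct_positive[match(ref$donor, tr$donor)],
                             ref$pct_positive)
      tibble::tibble(condition = cond, reference = "INFLAMED",
                     mean_ratio = pr$mean, sd_ratio = pr$sd,
                     convention = pr$convention)
    }))

  out <- list(
    elisa = list(amounts = fa, tiers = tiers, correlation = corr,
                 contrast = elisa_contrast, truth = elisa$truth),
    mirna = list(expression = expr, detected = det, quartile = quartile,
                 weights = weights, balance = balance,
                 contrast = mirna_contrast, truth = crt$truth),
    flow = list(folds = folds, polarization = polar_mean,
                positivity = positivity, truth = flow$truth),
    config = config
  )
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' Write the pipeline's tidy CSV outputs
#'
#' @param result list from [run_secretome_pipeline()].
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_csv(df, file.path(outdir, name))
  amounts_long <- tibble::as_tibble(result$elisa$amounts$amounts,
                                    rownames = "analyte") |>
    tidyr::pivot_longer(-"analyte", names_to = "sample",
                        values_to = "amount_pg_per_1e6_cells")
  w(amounts_long, "amounts.csv")
  w(result$elisa$tiers, "tiers.csv")
  corr_df <- dplyr::bind_rows(lapply(names(result$elisa$correlation), function(cond) {
    cc <- result$elisa$correlation[[cond]]
    tibble::tibble(condition = cond, mean_r = cc$mean, sd_r = cc$sd)
  }))
  w(corr_df, "correlation.csv")
  w(result$elisa$contrast, "contrast_factors.csv")
  expr_long <- tibble::as_tibble(result$mirna$expression$rel_expr,
                                 rownames = "mirna") |>
    tidyr::pivot_longer(-"mirna", names_to = "sample", values_to = "rel_expr")
  w(expr_long, "expression.csv")
  quart_df <- dplyr::bind_rows(lapply(names(result$mirna$quartile), function(cond) {
    tibble::tibble(condition = cond, mirna = as.character(result$mirna$quartile[[cond]]))
  }))
  w(quart_df, "quartile.csv")
  if (length(result$mirna$weights)) {
    weights_df <- dplyr::bind_rows(lapply(names(result$mirna$weights), function(cond) {
      dplyr::bind_rows(lapply(result$mirna$weights[[cond]], function(rep) {
        tibble::tibble(condition = cond, category = rep$name, weight_pct = rep$weight)
      }))
    }))
    w(weights_df, "weights.csv")
    w(result$mirna$balance, "balance.csv")
  }
  w(result$mirna$contrast, "contrast_mirnas.csv")
  w(result$flow$folds, "folds.csv")
  w(result$flow$polarization, "polarization.csv")
  w(result$flow$positivity, "positivity.csv")
  invisible(outdir)
}
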