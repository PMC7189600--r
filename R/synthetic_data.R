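# Synthetic paired-donor data with known ground truth. The generator emulates
# the study design every pipeline stage was built for: four donors assayed
# resting and primed, ~200 ELISA factors with log-normal abundances and an
# all-samples detection structure (57 resting / 58 primed detectable), a
# 754-miRNA two-panel qPCR array with spike-in offsets, amplification
# censoring at 28 cycles and a heavy-tailed abundance law whose first
# quartile dominates the message, and three-donor flow-cytometry readouts
# with configured true folds.

#' Configuration for the synthetic-data generator
#'
#' Defaults reproduce the study conditions: 4 donors, 200 assayed factors of
#' which 57 are detectable in all resting samples and 58 in all primed ones
#' (5 lost and 6 gained on priming), 754 miRNAs on two array panels with 242
#' resting-detectable and 222 primed-detectable (30 lost, 10 gained),
#' log-normal factor noise, a log-normal law over log2 miRNA abundance with
#' `sigma_log2 = 3.8` (placing ~95-97% of the message in the first quartile),
#' 0.25-cycle Gaussian Crt noise, a one-cycle panel-B spike-in offset, and
#' flow-cytometry true folds matching the validation readouts (CD86 1.41 and
#' CD163 0.74 under inflammation, CD163 rescue by secretome, VCAM1
#' suppression ratios 0.58 and 0.47).
#'
#' @param n_donors paired donors for the secretome layers (>= 2).
#' @param n_factors factors on the ELISA panel.
#' @param n_mirnas miRNAs across the two array panels.
#' @param seed base seed; every generator derives its stream from it.
#' @param factor_cv log-normal coefficient of variation of factor
#'   concentrations across donors (0 = noise-free limit).
#' @param factor_detect_both,factor_lost,factor_gained counts of factors
#'   detectable in both conditions, in resting only, in primed only.
#' @param factor_folds named map analyte -> true primed/resting fold for
#'   injected priming effects (applies to both-detectable factors).
#' @param assay_threshold,dilution_factor,medium_volume,cell_count culture
#'   and assay metadata passed through to the generated [factor_panel()].
#' @param mirna_detect_both,mirna_lost,mirna_gained counts of miRNAs
#'   detectable in both conditions, resting only, primed only.
#' @param mirna_folds named map miRNA index name -> true primed fold.
#' @param sigma_log2 SD of the log2-abundance law for detectable miRNAs.
#' @param crt_center mean Crt of a miRNA at the median abundance.
#' @param crt_limit amplification limit (cycles).
#' @param crt_noise_sd Gaussian noise on Crt, cycles (0 = noise-free).
#' @param spike_crt_a spike-in Crt on panel A.
#' @param panel_b_offset systematic Crt offset of panel B (cycles), carried
#'   identically by the panel-B spike-in and all panel-B targets.
#' @param category_sizes named integer vector: synthetic functional
#'   categories drawn from the both-detectable miRNAs.
#' @param flow_n_donors donors for the flow-cytometry layer.
#' @param flow_cv log-normal CV on net MFI and % positive (0 = noise-free).
#' @param flow_cd86,flow_cd163 named true net-MFI folds per macrophage
#'   condition (reference condition must have fold 1).
#' @param flow_vcam_pct named true % VCAM1-positive cells per chondrocyte
#'   condition.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_donors = 4,
                             n_factors = 200,
                             n_mirnas = 754,
                             seed = 1,
                             factor_cv = 0.2,
                             factor_detect_both = 52,
                             factor_lost = 5,
                             factor_gained = 6,
                             factor_folds = c(factor_001 = 3.71),
                             assay_threshold = 4,
                             dilution_factor = 2,
                             medium_volume = 5,
                             cell_count = 1e6,
                             mirna_detect_both = 212,
                             mirna_lost = 30,
                             mirna_gained = 10,
                             mirna_folds = NULL,
                             sigma_log2 = 3.8,
                             crt_center = 20,
                             crt_limit = 28,
                             crt_noise_sd = 0.25,
                             spike_crt_a = 15,
                             panel_b_offset = 1,
                             category_sizes = c(synthetic_protective = 10,
                                                synthetic_destructive = 7),
                             flow_n_donors = 3,
                             flow_cv = 0.1,
                             flow_cd86 = c(CTRL = 1, INFLAMED = 1.41,
                                           INFLAMED_SEC = 1.41,
                                           INFLAMED_PSEC = 1.30),
                             flow_cd163 = c(CTRL = 1, INFLAMED = 0.74,
                                            INFLAMED_SEC = 1.07,
                                            INFLAMED_PSEC = 1.18),
                             flow_vcam_pct = c(CTRL = 24, INFLAMED = 65,
                                               INFLAMED_SEC = 38,
                                               INFLAMED_PSEC = 31)) {
  cfg <- as.list(environment())
  if (n_donors < 2) stop("n_donors must be >= 2", call. = FALSE)
  if (factor_cv < 0 || flow_cv < 0 || crt_noise_sd < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (factor_detect_both + factor_lost + factor_gained > n_factors)
    stop("factor detectability counts exceed n_factors", call. = FALSE)
  if (mirna_detect_both + mirna_lost + mirna_gained > n_mirnas)
    stop("miRNA detectability counts exceed n_mirnas", call. = FALSE)
  if (any(c(factor_folds, mirna_folds, flow_cd86, flow_cd163) <= 0))
    stop("all true folds must be > 0", call. = FALSE)
  if (crt_limit <= 0) stop("crt_limit must be positive", call. = FALSE)
  if (sum(category_sizes) > mirna_detect_both)
    stop("category sizes exceed the both-detectable pool", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog))
}

sim_samples <- function(n_donors) {
  tibble::tibble(
    sample = c(paste0("D", seq_len(n_donors), "_R"),
               paste0("D", seq_len(n_donors), "_P")),
    donor = rep(paste0("D", seq_len(n_donors)), 2),
    condition = rep(c("resting", "primed"), each = n_donors)
  )
}

#' Generate a paired ELISA factor panel with known ground truth
#'
#' Detectable factors draw their baseline per-donor concentration from a
#' log-normal law around a per-factor median chosen well above the assay
#' threshold (log-uniform across the abundance tiers); factors not detectable
#' in a condition sit far below threshold there. Injected priming effects
#' multiply the primed concentration by the configured true fold.
#'
#' @param config a [synthetic_config()].
#' @return list with `panel` (a [factor_panel()] holding both conditions) and
#'   `truth` (tibble: analyte, median_pgml, true_fold, detectable_resting,
#'   detectable_primed).
#' @export
generate_elisa_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    analytes <- sprintf("factor_%03d", seq_len(config$n_factors))
    n_det <- config$factor_detect_both + config$factor_lost + config$factor_gained
    det_r <- rep(FALSE, config$n_factors)
    det_p <- rep(FALSE, config$n_factors)
    det_r[seq_len(config$factor_detect_both + config$factor_lost)] <- TRUE
    det_p[c(seq_len(config$factor_detect_both),
            config$factor_detect_both + config$factor_lost +
              seq_len(config$factor_gained))] <- TRUE
    # medians span the published abundance tiers (up to ~500 ng/10^6 cells,
    # conc = amount_pg / (dilution * volume)); the floor keeps detectable
    # medians 8x above the assay threshold so the all-samples rule holds
    # under the default donor noise
    min_ng <- max(0.05, 8 * config$assay_threshold * config$dilution_factor *
                    config$medium_volume / 1000)
    amount_ng <- 10^stats::runif(config$n_factors, log10(min_ng), log10(500))
    median_pgml <- amount_ng * 1000 / (config$dilution_factor * config$medium_volume)
    low_pgml <- config$assay_threshold / 8
    fold <- stats::setNames(rep(1, config$n_factors), analytes)
    known <- intersect(names(config$factor_folds), analytes)
    fold[known] <- config$factor_folds[known]
    samples <- sim_samples(config$n_donors)
    conc <- matrix(NA_real_, config$n_factors, nrow(samples),
                   dimnames = list(analytes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      primed <- samples$condition[j] == "primed"
      det <- if (primed) det_p else det_r
      med <- ifelse(det, median_pgml, low_pgml)
      eff <- if (primed) fold else rep(1, config$n_factors)
      conc[, j] <- med * eff * lognormal_noise(config$n_factors, config$factor_cv)
    }
    panel <- factor_panel(conc, samples,
                          assay_threshold = config$assay_threshold,
                          dilution_factor = config$dilution_factor,
                          medium_volume = config$medium_volume,
                          cell_count = config$cell_count)
    truth <- tibble::tibble(analyte = analytes, median_pgml = median_pgml,
                            true_fold = unname(fold),
                            detectable_resting = det_r,
                            detectable_primed = det_p)
    list(panel = panel, truth = truth)
  })
}

#' Generate a paired two-panel Crt table with known ground truth
#'
#' Detectable miRNAs draw a log2 relative abundance from a normal law with SD
#' `sigma_log2`, truncated below so the expected Crt stays at least two
#' cycles inside the amplification limit (guaranteeing the configured
#' detection counts under the default noise). `Crt = crt_center - log2
#' abundance + panel-B offset + noise`; miRNAs not detectable in a condition
#' emit Crt beyond the limit there and are removed by
#' [censor_unamplified()]. Synthetic functional categories are sampled from
#' the both-detectable pool.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (a [crt_table()]), `truth` (tibble: mirna,
#'   panel, log2_abundance, true_fold, detectable_resting,
#'   detectable_primed, category) and `categories` (list of
#'   [category_set()]).
#' @export
generate_crt_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_mirnas
    mirnas <- sprintf("mir_%04d", seq_len(n))
    panel_of <- stats::setNames(rep(c("A", "B"), length.out = n), mirnas)
    det_r <- rep(FALSE, n); det_p <- rep(FALSE, n)
    det_r[seq_len(config$mirna_detect_both + config$mirna_lost)] <- TRUE
    det_p[c(seq_len(config$mirna_detect_both),
            config$mirna_detect_both + config$mirna_lost +
              seq_len(config$mirna_gained))] <- TRUE
    # truncated normal on log2 abundance: keep E[Crt] <= limit - 2
    z_min <- config$crt_center - (config$crt_limit - 2)
    z <- stats::qnorm(stats::runif(n, stats::pnorm(z_min / config$sigma_log2), 1)) *
      config$sigma_log2
    fold <- stats::setNames(rep(1, n), mirnas)
    known <- intersect(names(config$mirna_folds), mirnas)
    fold[known] <- config$mirna_folds[known]
    samples <- sim_samples(config$n_donors)
    ns <- nrow(samples)
    crt <- matrix(NA_real_, n, ns, dimnames = list(mirnas, samples$sample))
    spike_crt <- matrix(NA_real_, ns, 2, dimnames = list(samples$sample, c("A", "B")))
    b_is <- panel_of == "B"
    for (j in seq_len(ns)) {
      primed <- samples$condition[j] == "primed"
      det <- if (primed) det_p else det_r
      zz <- z + if (primed) log2(fold) else 0
      base <- config$crt_center - zz
      base[!det] <- config$crt_limit + 1.5 + abs(base[!det] - config$crt_center) / 4
      b_off <- config$panel_b_offset +
        if (config$crt_noise_sd > 0) stats::rnorm(1, 0, config$crt_noise_sd) else 0
      noise <- if (config$crt_noise_sd > 0) stats::rnorm(n, 0, config$crt_noise_sd) else 0
      crt[, j] <- base + noise + b_off * b_is
      spike_crt[j, "A"] <- config$spike_crt_a
      spike_crt[j, "B"] <- config$spike_crt_a + b_off
    }
    x <- crt_table(crt, samples, panel_of, spike_crt)
    pool <- mirnas[seq_len(config$mirna_detect_both)]
    membership <- stats::setNames(rep(NA_character_, n), mirnas)
    picked <- sample(pool, sum(config$category_sizes))
    cats <- list()
    at <- 0
    for (nm in names(config$category_sizes)) {
      take <- picked[at + seq_len(config$category_sizes[[nm]])]
      at <- at + config$category_sizes[[nm]]
      membership[take] <- nm
      dir <- if (grepl("protective", nm)) "protective" else "destructive"
      cats[[nm]] <- category_set(nm, tibble::tibble(mirna = take, direction = dir))
    }
    truth <- tibble::tibble(mirna = mirnas, panel = unname(panel_of),
                            log2_abundance = z, true_fold = unname(fold),
                            detectable_resting = det_r,
                            detectable_primed = det_p,
                            category = unname(membership))
    list(table = x, truth = truth, categories = cats)
  })
}

#' Generate flow-cytometry summary readouts with known ground truth
#'
#' Per-donor macrophage MFIs (CD86/CD163 with unstained backgrounds) realize
#' the configured true net-MFI folds under log-normal noise, and chondrocyte
#' VCAM1 percent-positive values realize the configured condition means.
#'
#' @param config a [synthetic_config()].
#' @return list with `macrophage` (tibble: condition, marker, donor, mfi,
#'   unstained_mfi), `chondrocyte` (tibble: condition, donor, marker,
#'   pct_positive) and `truth`.
#' @export
generate_flow_readouts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 2L, {
    donors <- paste0("F", seq_len(config$flow_n_donors))
    base_net <- c(CD86 = 900, CD163 = 700)
    unstained <- 100
    marker_folds <- list(CD86 = config$flow_cd86, CD163 = config$flow_cd163)
    mac <- dplyr::bind_rows(lapply(names(marker_folds), function(mk) {
      folds <- marker_folds[[mk]]
      dplyr::bind_rows(lapply(names(folds), function(cond) {
        net <- base_net[[mk]] * folds[[cond]] *
          lognormal_noise(length(donors), config$flow_cv)
        tibble::tibble(condition = cond, marker = mk, donor = donors,
                       mfi = unstained + net, unstained_mfi = unstained)
      }))
    }))
    cho <- dplyr::bind_rows(lapply(names(config$flow_vcam_pct), function(cond) {
      pct <- pmin(100, config$flow_vcam_pct[[cond]] *
                    lognormal_noise(length(donors), config$flow_cv))
      tibble::tibble(condition = cond, donor = donors, marker = "VCAM1",
                     pct_positive = pct)
    }))
    list(macrophage = mac, chondrocyte = cho,
         truth = list(cd86 = config$flow_cd86, cd163 = config$flow_cd163,
                      vcam_pct = config$flow_vcam_pct))
  })
}
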