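# Primed-vs-resting contrast statistics shared by the factor and miRNA
# layers: per-donor ratios, one-sample t-test against a hypothetical mean of
# 1 (no modulation), Grubbs outlier screening, a Lilliefors-style normality
# check, significance calls, and a row-centered PCA utility.

#' Per-donor primed/resting ratios
#'
#' Ratios are computed separately for each donor (`primed / resting`) and
#' summarized as mean +/- SD, matching the paired four-donor design. Values
#' are paired by donor name when both vectors are named; otherwise they are
#' taken as position-paired. Donors with a zero or missing resting value have
#' no defined ratio and are excluded with a warning; a donor present in one
#' condition only is an error.
#'
#' @param resting,primed numeric vectors of per-donor values (named by donor
#'   where available).
#' @return list with `ratios` (named per donor), `mean`, `sd`, `n`.
#' @export
donor_ratios <- function(resting, primed) {
  if (!is.null(names(resting)) && !is.null(names(primed))) {
    if (!setequal(names(resting), names(primed)))
      stop(sprintf("unpaired donor(s): %s",
                   paste(union(setdiff(names(resting), names(primed)),
                               setdiff(names(primed), names(resting))),
                         collapse = ", ")), call. = FALSE)
    primed <- primed[names(resting)]
  } else if (length(resting) != length(primed)) {
    stop("resting and primed must pair one value per donor", call. = FALSE)
  }
  bad <- is.na(resting) | resting == 0 | is.na(primed)
  if (any(bad)) {
    warning(sprintf("%d donor(s) excluded (zero or missing value)", sum(bad)),
            call. = FALSE)
  }
  ratios <- (primed / resting)[!bad]
  list(ratios = ratios, mean = mean(ratios), sd = stats::sd(ratios),
       n = length(ratios))
}

#' One-sample t-test of mean ratio against 1
#'
#' Two-sided test of the donor ratios against a hypothetical mean of 1 (no
#' modulation), on the arithmetic ratio scale. Degenerate inputs follow fixed
#' conventions: all ratios exactly 1 gives p = 1; zero spread away from 1
#' gives p = 0 (with a message).
#'
#' @param ratios numeric vector of per-donor ratios, n >= 2.
#' @param log_scale test `log(ratios)` against 0 instead (off by default:
#'   the arithmetic scale is the reporting convention this test mirrors).
#' @return two-sided p-value.
#' @export
one_sample_t_vs_1 <- function(ratios, log_scale = FALSE) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2) stop("need at least 2 ratios", call. = FALSE)
  if (log_scale) ratios <- log(ratios)
  mu <- if (log_scale) 0 else 1
  s <- stats::sd(ratios)
  if (s == 0) {
    if (mean(ratios) == mu) return(1)
    message("zero spread with mean != null value; p set to 0 by convention")
    return(0)
  }
  stats::t.test(ratios, mu = mu)$p.value
}

#' Significance call for a priming contrast
#'
#' Encodes the reporting rules: `up` when the mean ratio exceeds the fold
#' threshold with p < alpha; `down` when it falls below the reciprocal with
#' p < alpha; `trend` when the fold criterion is met but alpha <= p <
#' trend_alpha (near-significant); otherwise `unchanged`. When the detection
#' flags differ between conditions, `gained` / `lost` override every other
#' call.
#'
#' @param mean_ratio mean primed/resting ratio.
#' @param p_value two-sided p-value from [one_sample_t_vs_1()] (may be `NA`
#'   when a detection override applies).
#' @param detected_resting,detected_primed detection flags per condition.
#' @param fold_threshold fold-change criterion (default 2).
#' @param alpha significance level (default 0.05).
#' @param trend_alpha near-significance level (default 0.1).
#' @return one of `"gained"`, `"lost"`, `"up"`, `"down"`, `"trend"`,
#'   `"unchanged"`.
#' @export
significance_call <- function(mean_ratio, p_value,
                              detected_resting = TRUE, detected_primed = TRUE,
                              fold_threshold = 2, alpha = 0.05,
                              trend_alpha = 0.1) {
  if (!detected_resting && detected_primed) return("gained")
  if (detected_resting && !detected_primed) return("lost")
  fold_met <- mean_ratio > fold_threshold || mean_ratio < 1 / fold_threshold
  if (!fold_met || is.na(p_value)) return("unchanged")
  if (p_value < alpha) return(if (mean_ratio > 1) "up" else "down")
  if (p_value < trend_alpha) return("trend")
  "unchanged"
}

#' Grubbs test for a single outlier
#'
#' Two-sided single-outlier Grubbs statistic `G = max|x - mean| / SD`,
#' compared against the critical value at level `alpha` derived from the
#' Student t quantile. At most one point is flagged per invocation; constant
#' data flags nothing.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with `index` (integer or `NA` when no outlier), `value`, `G`,
#'   `critical`.
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Grubbs test needs at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) return(list(index = NA_integer_, value = NA_real_, G = 0,
                          critical = NA_real_))
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  if (G > crit) {
    i <- which.max(dev)
    list(index = i, value = values[i], G = G, critical = crit)
  } else {
    list(index = NA_integer_, value = NA_real_, G = G, critical = crit)
  }
}

#' Lilliefors-style normality check
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal distribution with
#' the sample's own mean and SD; because the parameters are estimated, the
#' p-value comes from a Monte-Carlo null (samples of the same size from a
#' standard normal, same statistic), run under a fixed internal seed so the
#' check is reproducible. The RNG state of the caller is left untouched.
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @param nsim Monte-Carlo replicates (default 2000).
#' @param seed internal seed for the null draws.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_normality <- function(values, nsim = 2000, seed = 171717) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("normality check needs at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant values: SD is zero", call. = FALSE)
  lillie_d <- function(x) {
    z <- sort((x - mean(x)) / stats::sd(x))
    p <- stats::pnorm(z)
    i <- seq_along(z)
    max(i / length(z) - p, p - (i - 1) / length(z))
  }
  D <- lillie_d(values)
  null_d <- withr::with_seed(seed, {
    vapply(seq_len(nsim), function(i) lillie_d(stats::rnorm(n)), numeric(1))
  })
  list(statistic = D, p_value = (1 + sum(null_d >= D)) / (nsim + 1))
}

#' Row-centered principal component analysis
#'
#' Centers each row (analyte/miRNA) to zero mean and decomposes the centered
#' matrix by SVD; sample scores are returned per component with the fraction
#' of variance explained. Rows with any missing value are dropped (an
#' analysis is only defined on analytes measured in all samples). The sign of
#' each component is fixed so the loading with the largest magnitude is
#' positive.
#'
#' @param mat numeric matrix, analytes x samples.
#' @return list with `scores` (samples x components), `loadings` (analytes x
#'   components), `var_explained`, `sdev`.
#' @export
pca_row_centered <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  keep <- stats::complete.cases(mat)
  if (sum(keep) < 2) stop("fewer than 2 complete rows", call. = FALSE)
  x <- mat[keep, , drop = FALSE]
  x <- x - rowMeans(x)
  sv <- svd(x)
  flip <- apply(sv$u, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  u <- sweep(sv$u, 2, flip, "*")
  v <- sweep(sv$v, 2, flip, "*")
  scores <- sweep(v, 2, sv$d, "*")
  k <- seq_len(ncol(scores))
  dimnames(scores) <- list(colnames(mat), paste0("PC", k))
  dimnames(u) <- list(rownames(x), paste0("PC", k))
  tot <- sum(sv$d^2)
  list(scores = scores, loadings = u,
       var_explained = if (tot > 0) sv$d^2 / tot else rep(0, length(sv$d)),
       sdev = sv$d / sqrt(max(1, ncol(mat) - 1)))
}

#' Priming contrast over a value matrix
#'
#' Runs the full per-analyte contrast: optional Grubbs screening of the donor
#' ratios (a flagged ratio is removed, logged, and the test proceeds when at
#' least two ratios remain), one-sample t-test against 1, and the
#' significance call with gain/loss overrides from the detection flags. A
#' Benjamini-Hochberg adjusted column is emitted for information only; calls
#' are driven by the per-analyte p-values, mirroring the per-analyte
#' reporting convention.
#'
#' @param values analyte x sample matrix (per-cell amounts or relative
#'   expression).
#' @param samples sample metadata tibble (`sample`, `donor`, `condition`).
#' @param detected optional list of `resting` / `primed` detected identifier
#'   sets; rows absent from one set get `gained` / `lost` calls.
#' @param apply_grubbs screen donor ratios with [grubbs_outlier()] first
#'   (default `TRUE`).
#' @inheritParams significance_call
#' @return tibble of class `contrast_result`: analyte, n, mean_ratio,
#'   sd_ratio, p_value, q_value, call, outlier_removed.
#' @export
priming_contrast <- function(values, samples, detected = NULL,
                             apply_grubbs = TRUE, fold_threshold = 2,
                             alpha = 0.05, trend_alpha = 0.1) {
  r_idx <- samples$condition == "resting"
  p_idx <- samples$condition == "primed"
  r_donor <- samples$donor[r_idx]
  p_donor <- samples$donor[p_idx]
  rows <- lapply(rownames(values), function(an) {
    det_r <- if (is.null(detected)) TRUE else an %in% detected$resting
    det_p <- if (is.null(detected)) TRUE else an %in% detected$primed
    out <- tibble::tibble(analyte = an, n = NA_integer_, mean_ratio = NA_real_,
                          sd_ratio = NA_real_, p_value = NA_real_,
                          call = NA_character_, outlier_removed = FALSE)
    if (!det_r || !det_p) {
      out$call <- significance_call(NA, NA, det_r, det_p)
      return(out)
    }
    rest <- stats::setNames(values[an, r_idx], r_donor)
    prim <- stats::setNames(values[an, p_idx], p_donor)
    dr <- suppressWarnings(donor_ratios(rest, prim))
    ratios <- dr$ratios
    if (apply_grubbs && length(ratios) >= 3) {
      g <- grubbs_outlier(ratios)
      if (!is.na(g$index)) {
        ratios <- ratios[-g$index]
        out$outlier_removed <- TRUE
      }
    }
    out$n <- length(ratios)
    out$mean_ratio <- mean(ratios)
    out$sd_ratio <- stats::sd(ratios)
    if (length(ratios) >= 2 && out$sd_ratio >= 0)
      out$p_value <- one_sample_t_vs_1(ratios)
    out$call <- significance_call(out$mean_ratio, out$p_value, det_r, det_p,
                                  fold_threshold, alpha, trend_alpha)
    out
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- dplyr::relocate(res, "q_value", .after = "p_value")
  class(res) <- c("contrast_result", class(res))
  res
}
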