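# EV-miRNA layer: spike-in equalization of the two array panels, censoring at
# the amplification limit, global-mean dCrt normalization to relative
# expression 2^-dCrt, first-quartile selection, and genetic-weight scoring of
# functional categories.

DEFAULT_CRT_LIMIT <- 28

#' Equalize array panels via the spike-in reference
#'
#' The two array panels are run as independent reactions; the common spike-in
#' RNA anchors them. For each sample, every panel-B Crt is shifted by
#' `spike_crt[A] - spike_crt[B]` so both panels share the panel-A spike-in
#' reference; panel A is left unchanged. The choice of anchor is immaterial
#' for downstream dCrt values (any common anchor gives identical normalized
#' expression), which is asserted by the pipeline's invariance tests.
#'
#' @param x a [crt_table()].
#' @return a [crt_table()] with panel-B values shifted and the equalized flag
#'   set.
#' @export
spike_in_equalize <- function(x) {
  stopifnot(inherits(x, "crt_table"))
  on_b <- names(x$panel_of)[x$panel_of == "B"]
  offs <- x$spike_crt[, "A"] - x$spike_crt[, "B"]
  for (s in x$samples$sample) {
    has_b <- length(on_b) > 0 && any(!is.na(x$crt[on_b, s]))
    if (is.na(offs[s])) {
      if (has_b)
        stop(sprintf("sample '%s' needs spike-in Crt on both panels", s),
             call. = FALSE)
      next
    }
    if (length(on_b)) x$crt[on_b, s] <- x$crt[on_b, s] + offs[s]
    x$spike_crt[s, "B"] <- x$spike_crt[s, "B"] + offs[s]
  }
  attr(x, "equalized") <- TRUE
  x
}

#' Censor unamplified Crt values
#'
#' Crt values strictly greater than the amplification limit are treated as not
#' amplified and set to missing; a value exactly at the limit is retained.
#'
#' @param x a [crt_table()].
#' @param limit amplification limit in cycles (default 28).
#' @return a [crt_table()] with the censoring recorded.
#' @export
censor_unamplified <- function(x, limit = DEFAULT_CRT_LIMIT) {
  stopifnot(inherits(x, "crt_table"), limit > 0)
  x$crt[x$crt > limit] <- NA_real_
  attr(x, "censored_at") <- limit
  x
}

#' Global-mean normalization to relative expression
#'
#' For each sample, the global mean is the arithmetic mean of that sample's
#' amplified Crt values (the spike-in is never part of the target set);
#' `delta_crt = Crt - global mean` and `rel_expr = 2^-delta_crt`. By
#' construction the mean of `delta_crt` over a sample's amplified miRNAs is
#' zero, and adding any constant to all of a sample's Crt values leaves the
#' result unchanged.
#'
#' Censoring and panel equalization are expected to have been applied first
#' ([censor_unamplified()], [spike_in_equalize()]).
#'
#' @param x a [crt_table()].
#' @return object of class `expression_table`: list with matrices `delta_crt`
#'   and `rel_expr` (miRNA x sample, `NA` where not amplified), the `samples`
#'   tibble, `global_mean` per sample, and `never_amplified` (miRNAs with no
#'   amplified value in any sample, retained but flagged).
#' @export
global_mean_normalize <- function(x) {
  stopifnot(inherits(x, "crt_table"))
  gm <- colMeans(x$crt, na.rm = TRUE)
  empty <- colSums(!is.na(x$crt)) == 0
  if (any(empty))
    stop(sprintf("sample(s) with zero amplified miRNAs: %s",
                 paste(x$samples$sample[empty], collapse = ", ")), call. = FALSE)
  delta <- sweep(x$crt, 2, gm, "-")
  structure(
    list(delta_crt = delta, rel_expr = 2^-delta, samples = x$samples,
         global_mean = gm,
         never_amplified = rownames(x$crt)[rowSums(!is.na(x$crt)) == 0]),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d miRNAs x %d samples (%d never amplified)\n",
              nrow(x$rel_expr), ncol(x$rel_expr), length(x$never_amplified)))
  invisible(x)
}

#' Detected miRNA sets per condition
#'
#' A miRNA is detected in a condition only when it amplified in every sample
#' of that condition. Also reports the gain/loss vocabulary for priming:
#' `gained` = detected in primed only, `lost` = detected in resting only.
#'
#' @param expr an [global_mean_normalize()] expression table.
#' @return list of character vectors `resting`, `primed`, `both`, `gained`,
#'   `lost`.
#' @export
detected_sets <- function(expr) {
  sets <- lapply(CONDITIONS, function(cond) {
    idx <- expr$samples$condition == cond
    sub <- expr$rel_expr[, idx, drop = FALSE]
    rownames(sub)[rowSums(!is.na(sub)) == ncol(sub)]
  })
  names(sets) <- CONDITIONS
  list(resting = sets$resting, primed = sets$primed,
       both = intersect(sets$resting, sets$primed),
       gained = setdiff(sets$primed, sets$resting),
       lost = setdiff(sets$resting, sets$primed))
}

#' Mean relative expression per miRNA within a condition
#' @noRd
condition_mean_expr <- function(expr, condition) {
  idx <- expr$samples$condition == condition
  rowMeans(expr$rel_expr[, idx, drop = FALSE], na.rm = TRUE)
}

#' Select the first quartile of expression
#'
#' Ranks the condition's detected miRNAs by mean relative expression across
#' the condition's samples (descending) and keeps the top `ceiling(n / 4)`.
#' Ties at the cutoff break lexicographically by identifier so the selection
#' is deterministic.
#'
#' @param expr an expression table.
#' @param condition `"resting"` or `"primed"`.
#' @return character vector of selected miRNAs, with attributes `n_detected`
#'   and `n_selected`.
#' @export
first_quartile_select <- function(expr, condition = c("resting", "primed")) {
  condition <- match.arg(condition)
  det <- detected_sets(expr)[[condition]]
  if (!length(det)) stop("detected set is empty", call. = FALSE)
  m <- condition_mean_expr(expr, condition)[det]
  k <- ceiling(length(det) / 4)
  sel <- det[order(-m, det)][seq_len(k)]
  attr(sel, "n_detected") <- length(det)
  attr(sel, "n_selected") <- k
  sel
}

#' Genetic weight of a miRNA subset
#'
#' The genetic weight of a subset is its share, in percent, of the summed
#' relative expression of all miRNAs detected in the condition:
#' `100 * sum(subset mean rel_expr) / sum(detected mean rel_expr)`. By
#' default the mean relative expression is taken across the condition's
#' samples first, making the weight single-valued per condition
#' (`method = "condition_mean"`); `method = "per_sample"` instead computes the
#' weight within each sample and averages the per-sample weights.
#'
#' Subset members not in the condition's detected set contribute zero and are
#' reported with a warning.
#'
#' @param expr an expression table.
#' @param subset character vector of miRNA identifiers (or a
#'   [category_set()], whose members are used).
#' @param condition `"resting"` or `"primed"`.
#' @param method weighting variant, see Details.
#' @param name label for the report (defaults to the category name or
#'   `"subset"`).
#' @return object of class `genetic_weight_report`: list with `name`,
#'   `condition`, `weight` (%), `member_weights` (tibble: mirna, weight,
#'   detected), `selection`, `method`.
#' @export
genetic_weight <- function(expr, subset, condition = c("resting", "primed"),
                           method = c("condition_mean", "per_sample"),
                           name = NULL) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  if (inherits(subset, "category_set")) {
    name <- name %||% subset$name
    subset <- subset$entries$mirna
  }
  name <- name %||% "subset"
  det <- detected_sets(expr)[[condition]]
  missing <- setdiff(subset, det)
  if (length(missing))
    warning(sprintf("subset member(s) not detected in %s, contributing 0: %s",
                    condition, paste(missing, collapse = ", ")), call. = FALSE)
  inside <- intersect(subset, det)
  if (method == "condition_mean") {
    m <- condition_mean_expr(expr, condition)
    total <- sum(m[det])
    member <- 100 * m[inside] / total
    weight <- sum(member)
  } else {
    idx <- expr$samples$condition == condition
    sub <- expr$rel_expr[det, idx, drop = FALSE]
    sub[is.na(sub)] <- 0
    share <- sweep(sub, 2, colSums(sub), "/") * 100
    member <- rowMeans(share[inside, , drop = FALSE])
    weight <- mean(colSums(share[inside, , drop = FALSE]))
  }
  members <- tibble::tibble(
    mirna = c(inside, missing),
    weight = c(unname(member), rep(0, length(missing))),
    detected = c(rep(TRUE, length(inside)), rep(FALSE, length(missing)))
  )
  structure(list(name = name, condition = condition, weight = weight,
                 member_weights = members, selection = subset, method = method),
            class = "genetic_weight_report")
}

#' @export
print.genetic_weight_report <- function(x, ...) {
  cat(sprintf("<genetic_weight_report> %s (%s): %.2f%% of the genetic message (%d miRNAs)\n",
              x$name, x$condition, x$weight, nrow(x$member_weights)))
  invisible(x)
}

#' Balance between two category weights
#'
#' Compares two genetic-weight reports from the same condition (e.g. M2 vs M1
#' phenotype, cartilage-protective vs -destructive) and returns their
#' difference. When reports for a second condition are supplied, the change
#' of the delta between conditions is reported as well.
#'
#' @param report_a,report_b [genetic_weight_report]s for one condition.
#' @param report_a2,report_b2 optional reports for the other condition.
#' @return tibble with columns condition, name_a, weight_a, name_b, weight_b,
#'   delta; attribute `delta_change` when both conditions are given.
#' @export
category_balance <- function(report_a, report_b, report_a2 = NULL, report_b2 = NULL) {
  stopifnot(report_a$condition == report_b$condition)
  row <- function(a, b) tibble::tibble(
    condition = a$condition, name_a = a$name, weight_a = a$weight,
    name_b = b$name, weight_b = b$weight, delta = a$weight - b$weight
  )
  out <- row(report_a, report_b)
  if (!is.null(report_a2)) {
    stopifnot(report_a2$condition == report_b2$condition)
    out <- dplyr::bind_rows(out, row(report_a2, report_b2))
    attr(out, "delta_change") <- out$delta[2] - out$delta[1]
  }
  out
}
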