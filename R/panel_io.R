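# Input layer: delimited-text readers/writers and validated containers for the
# three raw data kinds (ELISA factor panels, qPCR-array Crt tables, functional
# category lists). Sample metadata (donor, condition) travels in a sidecar
# config, never encoded in column names.

# Reserved identifier for the exogenous spike-in RNA used to monitor technical
# variability and equalize array panels A and B.
SPIKE_IN_ID <- "ath-miR-159a"

CONDITIONS <- c("resting", "primed")

# Closed vocabulary for category direction labels. Table-style annotations use
# the phenotype-level labels; promoting/suppressing refinements are accepted
# where an annotation source provides them.
DIRECTION_VOCAB <- c(
  "protective", "destructive",
  "M1", "M2",
  "M1_promoting", "M1_suppressing", "M2_promoting", "M2_suppressing"
)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Construct an ELISA factor panel
#'
#' A `factor_panel` bundles an analyte x sample concentration matrix (pg/ml)
#' with the culture metadata needed to turn concentrations into per-cell
#' secreted amounts: dilution factor, conditioned-medium volume and cell count
#' at harvest. Concentrations below the per-analyte assay threshold stay in
#' the matrix; detection is decided downstream by [detection_filter()], never
#' by silently zeroing cells.
#'
#' @param conc numeric matrix, analytes in rows, samples in columns, pg/ml.
#'   `NA` marks a not-measured cell.
#' @param samples tibble with columns `sample`, `donor`, `condition`
#'   (`"resting"` or `"primed"`), one row per column of `conc`.
#' @param assay_threshold per-analyte minimum detectable concentration, pg/ml.
#'   A scalar is recycled to all analytes.
#' @param dilution_factor unitless dilution applied to supernatants before
#'   assay (>= 1).
#' @param medium_volume conditioned-medium volume per sample, ml. There is no
#'   default: the volume is a property of the culture run and must be supplied.
#' @param cell_count cells per sample at harvest; scalar or named per sample.
#' @return object of class `factor_panel`.
#' @export
factor_panel <- function(conc, samples, assay_threshold, dilution_factor,
                         medium_volume, cell_count) {
  conc <- as.matrix(conc)
  samples <- tibble::as_tibble(samples)
  analytes <- rownames(conc)
  if (is.null(analytes)) stop("`conc` must have analyte row names", call. = FALSE)
  if (is.null(names(assay_threshold))) {
    if (length(assay_threshold) == 1L)
      assay_threshold <- rep(assay_threshold, length(analytes))
    if (length(assay_threshold) != length(analytes))
      stop("assay_threshold must be scalar or one value per analyte", call. = FALSE)
    assay_threshold <- stats::setNames(assay_threshold, analytes)
  }
  if (is.null(names(cell_count))) {
    if (length(cell_count) == 1L) cell_count <- rep(cell_count, nrow(samples))
    if (length(cell_count) != nrow(samples))
      stop("cell_count must be scalar or one value per sample", call. = FALSE)
    cell_count <- stats::setNames(cell_count, samples$sample)
  }
  x <- structure(
    list(
      conc = conc, samples = samples,
      assay_threshold = assay_threshold[analytes],
      dilution_factor = dilution_factor,
      medium_volume = medium_volume,
      cell_count = cell_count[samples$sample]
    ),
    class = "factor_panel"
  )
  validate_factor_panel(x)
}

validate_factor_panel <- function(x) {
  conc <- x$conc
  if (any(conc < 0, na.rm = TRUE)) {
    bad <- which(conc < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative concentration for analyte '%s', sample '%s'",
                 rownames(conc)[bad[1]], colnames(conc)[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(conc)))
    stop("duplicate analyte identifiers", call. = FALSE)
  if (!identical(colnames(conc), x$samples$sample))
    stop("sample metadata does not match concentration columns", call. = FALSE)
  if (anyDuplicated(x$samples$sample))
    stop("duplicate sample identifiers", call. = FALSE)
  if (!all(x$samples$condition %in% CONDITIONS))
    stop("condition labels must be 'resting' or 'primed'", call. = FALSE)
  if (any(is.na(x$samples$donor)))
    stop("every sample needs a donor identifier", call. = FALSE)
  if (!is.numeric(x$dilution_factor) || x$dilution_factor < 1)
    stop("dilution_factor must be >= 1", call. = FALSE)
  if (!is.numeric(x$medium_volume) || any(x$medium_volume <= 0))
    stop("medium_volume must be positive", call. = FALSE)
  if (any(is.na(x$cell_count)) || any(x$cell_count <= 0))
    stop("cell_count must be positive for every sample", call. = FALSE)
  if (any(is.na(x$assay_threshold)))
    stop("assay_threshold missing for some analytes", call. = FALSE)
  x
}

#' @export
print.factor_panel <- function(x, ...) {
  cat(sprintf("<factor_panel> %d analytes x %d samples (%d resting, %d primed)\n",
              nrow(x$conc), ncol(x$conc),
              sum(x$samples$condition == "resting"),
              sum(x$samples$condition == "primed")))
  invisible(x)
}

#' Construct a qPCR-array Crt table
#'
#' Holds raw relative-threshold-cycle (Crt) values for miRNAs measured on two
#' array panels (A and B), plus the per-sample spike-in Crt for each panel.
#' Missing Crt means the target did not amplify in that sample.
#'
#' @param crt numeric matrix, miRNAs x samples, raw Crt cycles (`NA` = not
#'   amplified).
#' @param samples sample metadata tibble as for [factor_panel()].
#' @param panel_of named character vector mapping each miRNA to `"A"` or
#'   `"B"`.
#' @param spike_crt numeric matrix, samples x panels (columns `"A"`, `"B"`),
#'   spike-in Crt per sample and panel.
#' @return object of class `crt_table`.
#' @export
crt_table <- function(crt, samples, panel_of, spike_crt) {
  crt <- as.matrix(crt)
  samples <- tibble::as_tibble(samples)
  x <- structure(
    list(crt = crt, samples = samples, panel_of = panel_of[rownames(crt)],
         spike_crt = spike_crt),
    class = "crt_table"
  )
  attr(x, "censored_at") <- NA_real_
  attr(x, "equalized") <- FALSE
  validate_crt_table(x)
}

validate_crt_table <- function(x) {
  crt <- x$crt
  if (is.null(rownames(crt))) stop("`crt` must have miRNA row names", call. = FALSE)
  if (anyDuplicated(rownames(crt)))
    stop("duplicate miRNA identifiers", call. = FALSE)
  if (any(crt <= 0, na.rm = TRUE))
    stop("Crt values must be positive where present", call. = FALSE)
  if (!identical(colnames(crt), x$samples$sample))
    stop("sample metadata does not match Crt columns", call. = FALSE)
  if (!all(x$samples$condition %in% CONDITIONS))
    stop("condition labels must be 'resting' or 'primed'", call. = FALSE)
  if (any(is.na(x$panel_of)) || !all(x$panel_of %in% c("A", "B")))
    stop("every miRNA must be assigned to panel 'A' or 'B'", call. = FALSE)
  if (!all(c("A", "B") %in% colnames(x$spike_crt)))
    stop("spike_crt needs columns 'A' and 'B'", call. = FALSE)
  if (!identical(rownames(x$spike_crt), x$samples$sample))
    stop("spike_crt rows must match samples", call. = FALSE)
  # a spike-in value is required for every (sample, panel) that has data
  for (p in c("A", "B")) {
    on_panel <- names(x$panel_of)[x$panel_of == p]
    if (!length(on_panel)) next
    populated <- colSums(!is.na(crt[on_panel, , drop = FALSE])) > 0
    if (any(populated & is.na(x$spike_crt[, p])))
      stop(sprintf("missing spike-in Crt for panel %s in sample(s): %s", p,
                   paste(x$samples$sample[populated & is.na(x$spike_crt[, p])],
                         collapse = ", ")), call. = FALSE)
  }
  x
}

#' @export
print.crt_table <- function(x, ...) {
  cat(sprintf("<crt_table> %d miRNAs (%d panel A, %d panel B) x %d samples",
              nrow(x$crt), sum(x$panel_of == "A"), sum(x$panel_of == "B"),
              ncol(x$crt)))
  lim <- attr(x, "censored_at")
  if (!is.na(lim)) cat(sprintf("; censored at Crt > %g", lim))
  if (isTRUE(attr(x, "equalized"))) cat("; panel-B spike-equalized")
  cat("\n")
  invisible(x)
}

#' Construct a functional category set
#'
#' A named list of miRNAs annotated with a direction label (e.g. cartilage
#' `protective`/`destructive`, macrophage `M1`/`M2` phenotype) and optional
#' reference genetic-weight percentages for the resting-EV and primed-EV
#' conditions.
#'
#' @param name category label.
#' @param entries tibble with columns `mirna`, `direction`, and optionally
#'   `weight_resting`, `weight_primed` (reference % weights), `target_genes`,
#'   `note`.
#' @return object of class `category_set`.
#' @export
category_set <- function(name, entries) {
  entries <- tibble::as_tibble(entries)
  if (anyDuplicated(entries$mirna))
    stop(sprintf("duplicate miRNA within category '%s'", name), call. = FALSE)
  if (!all(entries$direction %in% DIRECTION_VOCAB))
    stop(sprintf("unknown direction label(s) in category '%s': %s", name,
                 paste(setdiff(entries$direction, DIRECTION_VOCAB), collapse = ", ")),
         call. = FALSE)
  structure(list(name = name, entries = entries), class = "category_set")
}

#' @export
print.category_set <- function(x, ...) {
  cat(sprintf("<category_set> %s: %d miRNAs\n", x$name, nrow(x$entries)))
  invisible(x)
}

read_meta <- function(meta) {
  if (is.character(meta) && length(meta) == 1L) meta <- yaml::read_yaml(meta)
  if (!is.list(meta)) stop("`meta` must be a list or a YAML file path", call. = FALSE)
  meta
}

meta_samples <- function(meta) {
  s <- meta$samples
  if (is.null(s)) stop("metadata must declare `samples`", call. = FALSE)
  if (is.data.frame(s)) return(tibble::as_tibble(s))
  dplyr::bind_rows(lapply(s, tibble::as_tibble))
}

parse_numeric_cells <- function(df, id_col) {
  num_cols <- setdiff(names(df), id_col)
  for (cn in num_cols) {
    raw <- df[[cn]]
    if (is.numeric(raw)) next
    raw <- trimws(as.character(raw))
    raw[raw == "" | toupper(raw) == "UNDETERMINED" | toupper(raw) == "NA"] <- NA
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': \"%s\"",
                   df[[id_col[1]]][bad[1]], cn, raw[bad[1]]), call. = FALSE)
    df[[cn]] <- val
  }
  df
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
}

#' Read an ELISA factor panel from a delimited-text file
#'
#' Expected layout: first column `analyte`, one further column per sample,
#' concentrations in pg/ml. Empty cells and `"Undetermined"` read as missing.
#' Culture metadata (donor/condition per sample, dilution factor, medium
#' volume, cell counts, assay thresholds) comes from a sidecar list or YAML
#' file, not from column-name conventions.
#'
#' @param path CSV (or TSV with `delim = "\t"`) file.
#' @param meta list or YAML path with elements `samples` (sample, donor,
#'   condition), `dilution_factor`, `medium_volume`, `cell_count`,
#'   `assay_threshold`.
#' @param delim field delimiter, `","` by default.
#' @return a [factor_panel()].
#' @export
read_factor_panel <- function(path, meta, delim = ",") {
  stopifnot(file.exists(path))
  meta <- read_meta(meta)
  df <- read_delim_quiet(path, delim)
  if (names(df)[1] != "analyte")
    stop("first column must be named 'analyte'", call. = FALSE)
  df <- parse_numeric_cells(df, "analyte")
  conc <- as.matrix(df[, -1])
  rownames(conc) <- df$analyte
  samples <- meta_samples(meta)
  conc <- conc[, samples$sample, drop = FALSE]
  thr <- meta$assay_threshold
  if (is.list(thr)) thr <- unlist(thr)
  cells <- meta$cell_count
  if (is.list(cells)) cells <- unlist(cells)
  if (is.null(meta$medium_volume))
    stop("metadata must supply `medium_volume` (ml); it is never defaulted",
         call. = FALSE)
  factor_panel(conc, samples,
               assay_threshold = thr,
               dilution_factor = meta$dilution_factor %||% 1,
               medium_volume = meta$medium_volume,
               cell_count = cells)
}

#' Write a factor panel back to delimited text (plus YAML metadata)
#'
#' @param x a [factor_panel()].
#' @param path output CSV path.
#' @param meta_path optional YAML path for the sidecar metadata.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_factor_panel <- function(x, path, meta_path = NULL, delim = ",") {
  df <- tibble::as_tibble(x$conc, rownames = "analyte")
  readr::write_delim(df, path, delim = delim, na = "")
  if (!is.null(meta_path)) {
    yaml::write_yaml(list(
      samples = lapply(seq_len(nrow(x$samples)), function(i) as.list(x$samples[i, ])),
      dilution_factor = x$dilution_factor,
      medium_volume = x$medium_volume,
      cell_count = as.list(x$cell_count),
      assay_threshold = as.list(x$assay_threshold)
    ), meta_path)
  }
  invisible(path)
}

#' Read a qPCR-array Crt table from a delimited-text file
#'
#' Expected layout: columns `mirna`, `panel` (A/B), then one column per
#' sample with raw Crt values. Rows whose identifier equals the reserved
#' spike-in name (`ath-miR-159a`) are extracted into the per-sample,
#' per-panel spike-in slots and are not kept among the miRNAs. Empty cells
#' and `"Undetermined"` read as not amplified.
#'
#' @inheritParams read_factor_panel
#' @param spike_id reserved spike-in identifier.
#' @return a [crt_table()].
#' @export
read_crt_table <- function(path, meta, delim = ",", spike_id = SPIKE_IN_ID) {
  stopifnot(file.exists(path))
  meta <- read_meta(meta)
  df <- read_delim_quiet(path, delim)
  if (!all(c("mirna", "panel") %in% names(df)[1:2]))
    stop("first two columns must be 'mirna' and 'panel'", call. = FALSE)
  if (any(is.na(df$panel) | !(df$panel %in% c("A", "B"))))
    stop(sprintf("miRNA without valid panel assignment: %s",
                 paste(df$mirna[is.na(df$panel) | !(df$panel %in% c("A", "B"))],
                       collapse = ", ")), call. = FALSE)
  df <- parse_numeric_cells(df, c("mirna", "panel"))
  samples <- meta_samples(meta)
  is_spike <- df$mirna == spike_id
  spike <- df[is_spike, ]
  body <- df[!is_spike, ]
  if (anyDuplicated(body$mirna))
    stop("duplicate miRNA identifiers", call. = FALSE)
  crt <- as.matrix(body[, samples$sample, drop = FALSE])
  rownames(crt) <- body$mirna
  spike_crt <- matrix(NA_real_, nrow = nrow(samples), ncol = 2,
                      dimnames = list(samples$sample, c("A", "B")))
  for (i in seq_len(nrow(spike))) {
    spike_crt[, spike$panel[i]] <- as.numeric(spike[i, samples$sample])
  }
  crt_table(crt, samples,
            panel_of = stats::setNames(body$panel, body$mirna),
            spike_crt = spike_crt)
}

#' Write a Crt table back to delimited text (plus YAML metadata)
#'
#' Spike-in values are re-emitted as reserved-identifier rows, one per panel.
#'
#' @param x a [crt_table()].
#' @inheritParams write_factor_panel
#' @param spike_id reserved spike-in identifier.
#' @return `path`, invisibly.
#' @export
write_crt_table <- function(x, path, meta_path = NULL, delim = ",",
                            spike_id = SPIKE_IN_ID) {
  body <- tibble::as_tibble(x$crt, rownames = "mirna")
  body <- tibble::add_column(body, panel = unname(x$panel_of), .after = "mirna")
  spike_rows <- lapply(c("A", "B"), function(p) {
    if (all(is.na(x$spike_crt[, p]))) return(NULL)
    row <- tibble::as_tibble(as.list(x$spike_crt[, p]))
    tibble::add_column(row, mirna = spike_id, panel = p, .before = 1)
  })
  out <- dplyr::bind_rows(c(spike_rows, list(body)))
  readr::write_delim(out, path, delim = delim, na = "")
  if (!is.null(meta_path)) {
    yaml::write_yaml(list(
      samples = lapply(seq_len(nrow(x$samples)), function(i) as.list(x$samples[i, ]))
    ), meta_path)
  }
  invisible(path)
}

#' Read functional category annotations
#'
#' Expected layout: columns `category`, `mirna`, `direction`, and optionally
#' `weight_ev_pct`/`weight_iev_pct` (reference % genetic weights for the
#' resting-EV and primed-EV conditions), `target_genes`, `note`. Returns one
#' [category_set()] per distinct category. Two packaged fixtures transcribe
#' the published cartilage-protective/destructive and macrophage-M1/M2
#' first-quartile annotation tables; see
#' `system.file("extdata", package = "secretomix")`.
#'
#' @inheritParams read_factor_panel
#' @return named list of [category_set()] objects (empty list for an empty
#'   file).
#' @export
read_category_sets <- function(path, delim = ",") {
  stopifnot(file.exists(path))
  df <- read_delim_quiet(path, delim)
  if (nrow(df) == 0) return(list())
  need <- c("category", "mirna", "direction")
  if (!all(need %in% names(df)))
    stop("category file needs columns: category, mirna, direction", call. = FALSE)
  for (wc in intersect(c("weight_ev_pct", "weight_iev_pct"), names(df)))
    df[[wc]] <- as.numeric(df[[wc]])
  col_or <- function(d, nm, default) if (nm %in% names(d)) d[[nm]] else default
  out <- lapply(split(df, df$category), function(d) {
    entries <- tibble::tibble(
      mirna = d$mirna,
      direction = d$direction,
      weight_resting = col_or(d, "weight_ev_pct", NA_real_),
      weight_primed = col_or(d, "weight_iev_pct", NA_real_),
      target_genes = col_or(d, "target_genes", NA_character_),
      note = col_or(d, "note", NA_character_)
    )
    category_set(d$category[1], entries)
  })
  out[unique(df$category)]
}

#' Sum the reference genetic weights stored with a category set
#'
#' Annotation tables carry each member's published share (%) of the total
#' genetic message per condition; the category's weight is the plain sum of
#' its members' shares.
#'
#' @param x a [category_set()].
#' @param condition `"resting"` or `"primed"`.
#' @return numeric scalar, percent.
#' @export
reference_weight <- function(x, condition = c("resting", "primed")) {
  condition <- match.arg(condition)
  col <- if (condition == "resting") "weight_resting" else "weight_primed"
  w <- x$entries[[col]]
  if (all(is.na(w)))
    stop(sprintf("category '%s' carries no reference weights for %s",
                 x$name, condition), call. = FALSE)
  sum(w, na.rm = TRUE)
}
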