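# Cell-type enrichment scoring of promoters/TFs against a sample panel.

#' Construct an expression panel
#'
#' An expression panel holds a TPM matrix (rows: genes or promoters, columns:
#' samples), the identity of the focal sample whose enrichment is of interest,
#' and per-row metadata.
#'
#' @param tpm Numeric matrix of TPM values with unique rownames (feature ids)
#'   and colnames (sample ids). All values must be non-negative.
#' @param focal_sample Column name of the focal sample.
#' @param meta Optional data frame with columns `id`, `symbol`, `is_tf`.
#'   Defaults to ids as symbols and `is_tf = FALSE`.
#'
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(tpm, focal_sample, meta = NULL) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    abort_arg("`tpm` must be a numeric matrix")
  }
  if (is.null(rownames(tpm)) || anyDuplicated(rownames(tpm))) {
    abort_arg("`tpm` must have unique rownames")
  }
  if (is.null(colnames(tpm))) abort_arg("`tpm` must have colnames (sample ids)")
  if (any(tpm < 0)) abort_arg("TPM values must be non-negative")
  if (!focal_sample %in% colnames(tpm)) {
    abort_arg(sprintf("focal sample '%s' is not a column of the panel", focal_sample))
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(id = rownames(tpm), symbol = rownames(tpm), is_tf = FALSE)
  } else {
    meta <- tibble::as_tibble(meta)
    need <- c("id", "symbol", "is_tf")
    miss <- setdiff(need, names(meta))
    if (length(miss)) abort_arg(paste0("`meta` is missing column(s): ", paste(miss, collapse = ", ")))
    if (!identical(sort(meta$id), sort(rownames(tpm)))) {
      abort_arg("`meta$id` must match the rownames of `tpm`")
    }
    meta <- meta[match(rownames(tpm), meta$id), ]
  }
  structure(list(tpm = tpm, focal_sample = focal_sample, meta = meta),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d features x %d samples (focal: %s, %d TF rows)\n",
              nrow(x$tpm), ncol(x$tpm), x$focal_sample, sum(x$meta$is_tf)))
  invisible(x)
}

#' Cell-type enrichment score
#'
#' The enrichment score of a feature is the log10 ratio of its pseudocounted
#' expression in the focal sample to its pseudocounted median across the panel:
#' `log10((tpm_focal + 1) / (median_panel + 1))`.  A score of 1.25 corresponds
#' to roughly an 18-fold enrichment over the panel median.
#'
#' @param tpm_focal Expression (TPM) in the focal sample; non-negative.
#' @param median_panel Median expression (TPM) across the panel; non-negative.
#'
#' @return Numeric vector of scores (log10 units).
#' @export
enrichment_score <- function(tpm_focal, median_panel) {
  if (!is.numeric(tpm_focal) || !is.numeric(median_panel)) {
    abort_arg("inputs must be numeric")
  }
  if (any(tpm_focal < 0, na.rm = TRUE) || any(median_panel < 0, na.rm = TRUE)) {
    abort_arg("expression values must be non-negative")
  }
  log10((tpm_focal + 1) / (median_panel + 1))
}

# Per-row focal expression, panel median and score for a panel.
panel_scores <- function(panel, include_focal = TRUE) {
  stopifnot(inherits(panel, "expression_panel"))
  cols <- colnames(panel$tpm)
  if (!include_focal) cols <- setdiff(cols, panel$focal_sample)
  med <- apply(panel$tpm[, cols, drop = FALSE], 1L, stats::median)
  tibble::tibble(
    id = panel$meta$id,
    symbol = panel$meta$symbol,
    is_tf = panel$meta$is_tf,
    tpm_focal = panel$tpm[, panel$focal_sample],
    median_panel = med,
    score = enrichment_score(panel$tpm[, panel$focal_sample], med)
  )
}

#' Rank transcription factors by cell-type enrichment
#'
#' Restricts the panel to TF rows and sorts them by descending enrichment
#' score.  Ties are broken by descending focal TPM, then by id, so the
#' ordering is deterministic and invariant to the input row order.
#'
#' @param panel An [expression_panel()].
#' @param include_focal Include the focal sample when taking the panel median
#'   (the default); set `FALSE` to take the median over the other samples only.
#'
#' @return A tibble with columns `id`, `symbol`, `tpm_focal`, `median_panel`,
#'   `score`, `rank` (1 = most enriched), sorted by rank.
#' @export
rank_tfs <- function(panel, include_focal = TRUE) {
  sc <- panel_scores(panel, include_focal = include_focal)
  sc <- sc[sc$is_tf, , drop = FALSE]
  if (nrow(sc) == 0L) abort_data("panel contains no TF rows")
  sc <- dplyr::arrange(sc, dplyr::desc(.data$score), dplyr::desc(.data$tpm_focal), .data$id)
  sc$rank <- seq_len(nrow(sc))
  sc[, c("id", "symbol", "tpm_focal", "median_panel", "score", "rank")]
}

#' Cell-type-enriched promoter set
#'
#' Returns the ids of features whose focal expression exceeds `fold_threshold`
#' times their panel median.  By default the same pseudocounted ratio as
#' [enrichment_score()] is used, `(x + 1) / (m + 1)`, which stays defined at
#' zero medians; set `pseudocount = FALSE` for the raw ratio `x / m` (which
#' requires positive medians).
#'
#' @param panel An [expression_panel()].
#' @param fold_threshold Ratio above which a feature is called enriched (> 1).
#' @param pseudocount Use the pseudocounted ratio (default `TRUE`).
#' @param include_focal Include the focal sample in the panel median.
#'
#' @return Character vector of enriched feature ids.
#' @export
enriched_promoters <- function(panel, fold_threshold = 3, pseudocount = TRUE,
                               include_focal = TRUE) {
  assert_scalar_number(fold_threshold, "fold_threshold", min = 1, strict_min = TRUE)
  sc <- panel_scores(panel, include_focal = include_focal)
  if (pseudocount) {
    ratio <- (sc$tpm_focal + 1) / (sc$median_panel + 1)
  } else {
    if (any(sc$median_panel <= 0)) {
      abort_data("raw-ratio mode requires positive panel medians for all rows")
    }
    ratio <- sc$tpm_focal / sc$median_panel
  }
  sc$id[ratio > fold_threshold]
}

#' Fraction of a gene set detected in the focal sample
#'
#' A gene-set member counts as detected if its focal-sample expression is at
#' least `tpm_threshold`.  Members absent from the panel count as undetected
#' and are reported (with a warning).
#'
#' @param panel An [expression_panel()].
#' @param gene_set Character vector of gene symbols (or ids, see `by`).
#' @param tpm_threshold Detection threshold in TPM (default 5).
#' @param by Match the set against row `"symbol"` (default) or `"id"`.
#'
#' @return A list with `fraction` (detected / set size), `detected`,
#'   `undetected` and `missing` (set members absent from the panel).
#' @export
gene_set_detection <- function(panel, gene_set, tpm_threshold = 5,
                               by = c("symbol", "id")) {
  by <- match.arg(by)
  if (length(gene_set) == 0L) abort_arg("`gene_set` must be non-empty")
  gene_set <- unique(as.character(gene_set))
  sc <- panel_scores(panel)
  key <- if (by == "symbol") sc$symbol else sc$id
  present <- gene_set[gene_set %in% key]
  missing <- setdiff(gene_set, present)
  if (length(missing)) {
    rlang::warn(sprintf("%d of %d gene-set members are absent from the panel",
                        length(missing), length(gene_set)))
  }
  focal <- sc$tpm_focal[match(present, key)]
  detected <- present[focal >= tpm_threshold]
  list(
    fraction = length(detected) / length(gene_set),
    detected = detected,
    undetected = c(setdiff(present, detected), missing),
    missing = missing
  )
}
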