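# Perturbation edge calling from a TF-knock-down x target qRT-PCR
# fold-change matrix (matrix-RNAi design).

#' Call perturbation edges from a fold-change matrix
#'
#' Replicate fold changes per (TF, target) cell are averaged as a geometric
#' mean (arithmetic mean in log2 space, since fold changes are ratios).  A
#' cell yields an `up` edge if the mean fold change is at least `threshold`
#' and a `down` edge if it is at most `1/threshold`.  Self cells (a TF
#' measured in its own knock-down) are excluded from edge calling; they carry
#' knock-down efficiency instead (see [kd_efficiency()]).
#'
#' @param fc Long-format data frame with columns `target`, `tf`,
#'   `fold_change` and optionally `replicate`; all fold changes must be
#'   positive (linear scale, relative to scrambled control).
#' @param threshold Fold-change threshold (> 1; default 1.5).
#' @param per_replicate If `TRUE`, require every replicate (not just the
#'   mean) to clear the threshold in the same direction.
#'
#' @return Tibble of edges: `tf`, `target`, `mean_fold_change`, `sd_log2`,
#'   `sign` (`"up"`/`"down"`), `n_replicates`.
#' @export
call_edges <- function(fc, threshold = 1.5, per_replicate = FALSE) {
  assert_scalar_number(threshold, "threshold", min = 1, strict_min = TRUE)
  fc <- tibble::as_tibble(fc)
  need <- c("target", "tf", "fold_change")
  miss <- setdiff(need, names(fc))
  if (length(miss)) abort_arg(paste0("`fc` is missing column(s): ", paste(miss, collapse = ", ")))
  bad <- !is.finite(fc$fold_change) | fc$fold_change <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    abort_data(sprintf("non-positive fold change in cell (tf=%s, target=%s)",
                       fc$tf[i], fc$target[i]))
  }
  cells <- fc |>
    dplyr::group_by(.data$tf, .data$target) |>
    dplyr::summarise(
      mean_fold_change = 2^mean(log2(.data$fold_change)),
      sd_log2 = stats::sd(log2(.data$fold_change)),
      min_fc = min(.data$fold_change),
      max_fc = max(.data$fold_change),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$tf != .data$target)
  if (per_replicate) {
    up <- cells$min_fc >= threshold
    down <- cells$max_fc <= 1 / threshold
  } else {
    up <- cells$mean_fold_change >= threshold
    down <- cells$mean_fold_change <= 1 / threshold
  }
  cells$sign <- dplyr::case_when(up ~ "up", down ~ "down", TRUE ~ NA_character_)
  out <- cells[!is.na(cells$sign),
               c("tf", "target", "mean_fold_change", "sd_log2", "sign", "n_replicates")]
  dplyr::arrange(out, .data$tf, .data$target)
}

#' Summarize network hierarchy from a perturbation edge list
#'
#' Out-degree is the number of targets affected by a TF's knock-down (split
#' by direction); in-degree is the number of knock-downs affecting a target.
#' A TF whose edges are all up-signed is flagged `all_up` (an antagonist
#' pattern), and symmetrically for `all_down`.
#'
#' @param edges Edge tibble from [call_edges()].
#' @param tfs,targets Optional full TF / target panels so that zero degrees
#'   are reported for members without edges.
#'
#' @return List with `out_degree` (tibble `tf`, `n_up`, `n_down`,
#'   `out_degree`, `all_up`, `all_down`, sorted by descending out-degree) and
#'   `in_degree` (tibble `target`, `in_degree`).
#' @export
degree_summary <- function(edges, tfs = NULL, targets = NULL) {
  edges <- tibble::as_tibble(edges)
  tfs <- unique(c(tfs, edges$tf))
  targets <- unique(c(targets, edges$target))
  out <- tibble::tibble(tf = tfs) |>
    dplyr::left_join(
      edges |>
        dplyr::group_by(.data$tf) |>
        dplyr::summarise(n_up = sum(.data$sign == "up"),
                         n_down = sum(.data$sign == "down"), .groups = "drop"),
      by = "tf"
    ) |>
    dplyr::mutate(
      n_up = dplyr::coalesce(.data$n_up, 0L),
      n_down = dplyr::coalesce(.data$n_down, 0L),
      out_degree = .data$n_up + .data$n_down,
      all_up = .data$out_degree > 0L & .data$n_down == 0L,
      all_down = .data$out_degree > 0L & .data$n_up == 0L
    ) |>
    dplyr::arrange(dplyr::desc(.data$out_degree), .data$tf)
  indeg <- tibble::tibble(target = targets) |>
    dplyr::left_join(
      edges |>
        dplyr::group_by(.data$target) |>
        dplyr::summarise(in_degree = dplyr::n(), .groups = "drop"),
      by = "target"
    ) |>
    dplyr::mutate(in_degree = dplyr::coalesce(.data$in_degree, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$in_degree), .data$target)
  list(out_degree = out, in_degree = indeg)
}

#' Knock-down efficiency per TF
#'
#' The residual expression of a TF in its own knock-down is the geometric
#' mean fold change of the TF's own row in its own column.  Residuals are
#' classified `efficient` (< 0.5), `suboptimal` (0.5-0.77) or `failed`
#' (> 0.77); TFs not measured in the target panel are reported as `NA`.
#'
#' @param fc Long-format fold-change table (see [call_edges()]).
#' @param tfs TFs to report (default: every perturbed TF in `fc`).
#'
#' @return Tibble `tf`, `residual`, `class`.
#' @export
kd_efficiency <- function(fc, tfs = NULL) {
  fc <- tibble::as_tibble(fc)
  tfs <- tfs %||% unique(fc$tf)
  own <- fc[fc$tf == fc$target & fc$tf %in% tfs, ]
  res <- own |>
    dplyr::group_by(tf = .data$tf) |>
    dplyr::summarise(residual = 2^mean(log2(.data$fold_change)), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(tf = tfs), res, by = "tf")
  out$class <- dplyr::case_when(
    is.na(out$residual) ~ NA_character_,
    out$residual < 0.5 ~ "efficient",
    out$residual <= 0.77 ~ "suboptimal",
    TRUE ~ "failed"
  )
  out
}
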