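# Pro-/anti-state and activator/repressor classification of perturbed TFs
# from their DE result and the enriched-promoter partition.

#' Cross-tabulate DE sets against the enriched-promoter partition
#'
#' @param up,down Character vectors of up- and down-regulated promoter ids
#'   (disjoint, both subsets of `universe`).
#' @param enriched Character vector of cell-type-enriched promoter ids.
#' @param universe All promoters tested for differential expression.
#'
#' @return Named integer vector `(up_enr, up_non, down_enr, down_non)`.
#' @export
partition_2x2 <- function(up, down, enriched, universe) {
  if (length(intersect(up, down))) {
    abort_data("up and down sets overlap")
  }
  if (!all(up %in% universe) || !all(down %in% universe)) {
    abort_data("DE sets must be subsets of the universe")
  }
  enriched <- intersect(enriched, universe)
  c(up_enr = length(intersect(up, enriched)),
    up_non = length(setdiff(up, enriched)),
    down_enr = length(intersect(down, enriched)),
    down_non = length(setdiff(down, enriched)))
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` is the number of marked items in a draw of `n` from
#' a population of `N` containing `K` marked items.  Computed via the
#' log-space cumulative hypergeometric for numerical stability.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Marked items in the population.
#' @param n Draw size.
#' @param N Population size.
#'
#' @return The tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(K, n)
  if (!all(ok)) abort_arg("inconsistent hypergeometric arguments")
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Up/down regulation ratio
#'
#' @param n_up,n_down Promoter counts.
#' @return `n_up / n_down`; `Inf` (with a warning) when `n_down` is 0 and
#'   `n_up` > 0, `NaN` (with a warning) when both are 0.
#' @export
ud_ratio <- function(n_up, n_down) {
  if (n_down == 0 && n_up == 0) {
    rlang::warn("both counts are zero; ratio undefined")
    return(NaN)
  }
  if (n_down == 0) {
    rlang::warn("no down-regulated promoters; ratio is infinite")
    return(Inf)
  }
  n_up / n_down
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' `chi2 = N * (|ad - bc| - N/2)^2 / (r1 * r2 * c1 * c2)`, clamped at 0 when
#' `|ad - bc| <= N/2`, with a p-value from the chi-square distribution on one
#' degree of freedom.  Tables with a zero margin are skipped (statistic `NA`,
#' with a warning).
#'
#' @param table A 2x2 matrix or a length-4 vector `(a, b, c, d)` read
#'   row-wise.
#'
#' @return List with `statistic`, `p_value` and `skipped`.
#' @export
chi2_yates <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L || any(x < 0)) abort_arg("`table` must be 4 non-negative counts")
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  n <- sum(x)
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    rlang::warn("zero margin; chi-square test skipped")
    return(list(statistic = NA_real_, p_value = NA_real_, skipped = TRUE))
  }
  dev <- max(abs(a * d - b * c_) - n / 2, 0)
  stat <- n * dev^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       skipped = FALSE)
}

#' Classify a TF as pro-state, anti-state or neutral
#'
#' From the 2x2 table of up/down x enriched/non-enriched promoters, the
#' ratio of ratios `(up_enr / up_non) / (down_enr / down_non)` measures which
#' direction the enriched promoters skew.  A significant Yates chi-square
#' with a ratio of ratios below 1 (enriched promoters skewed toward
#' down-regulation on knock-down) calls the TF `pro`; above 1 calls `anti`;
#' otherwise `neutral`.
#'
#' @param table Output of [partition_2x2()] (or any 4 counts in that order).
#' @param alpha Significance level for the chi-square test.
#'
#' @return List with `call` (`"pro"`, `"anti"` or `"neutral"`),
#'   `ratio_of_ratios`, `chi2` and `p_value`.
#' @export
classify_state <- function(table, alpha = 0.05) {
  x <- as.numeric(table)
  if (length(x) != 4L) abort_arg("`table` must be the 4 counts (up_enr, up_non, down_enr, down_non)")
  chi <- chi2_yates(x)
  ror <- (x[1L] / x[2L]) / (x[3L] / x[4L])
  # ror = 0 (all-enriched skew down) and ror = Inf (all-enriched skew up)
  # are legitimate extreme pro/anti patterns; only 0/0 is undecidable.
  call <- if (!isTRUE(chi$p_value < alpha) || is.nan(ror) || ror == 1) {
    "neutral"
  } else if (ror < 1) "pro" else "anti"
  list(call = call, ratio_of_ratios = ror,
       chi2 = chi$statistic, p_value = chi$p_value)
}

#' Classify a TF as activator, repressor or mixed
#'
#' A TF whose knock-down yields at least `fold` times as many down- as
#' up-regulated promoters is called an `activator`; the reverse pattern a
#' `repressor`; anything in between `mixed`.
#'
#' @param n_up,n_down Total up-/down-regulated promoter counts.
#' @param fold Required imbalance (default 2).
#'
#' @return `"activator"`, `"repressor"` or `"mixed"`.
#' @export
classify_regulator <- function(n_up, n_down, fold = 2) {
  if (n_up < 0 || n_down < 0) abort_arg("counts must be non-negative")
  if (n_down >= fold * n_up && n_down > 0) return("activator")
  if (n_up >= fold * n_down && n_up > 0) return("repressor")
  "mixed"
}

#' Per-TF state table
#'
#' Assembles, for one TF knock-down, the 2x2 partition of its DE sets
#' against the enriched-promoter set, the hypergeometric enrichment
#' p-values (perturbed, up and down sets against the enriched set), the
#' up/down ratios within the enriched (`ud_ratio_enr`) and non-enriched
#' (`ud_ratio_non`) compartments, the Yates chi-square, and the state and
#' regulator calls.  Note `ratio_of_ratios = ud_ratio_enr / ud_ratio_non`.
#'
#' @inheritParams partition_2x2
#' @param alpha Significance level for the state call.
#' @param fold Imbalance threshold for the regulator call.
#'
#' @return One-row tibble with counts, statistics and calls.
#' @export
state_table <- function(up, down, enriched, universe, alpha = 0.05, fold = 2) {
  tab <- partition_2x2(up, down, enriched, universe)
  enr <- intersect(enriched, universe)
  n_univ <- length(unique(universe))
  k_enr <- length(enr)
  perturbed <- union(up, down)
  hyper <- function(set) {
    if (!length(set)) return(1)
    hypergeom_tail(length(intersect(set, enr)), k_enr, length(set), n_univ)
  }
  st <- classify_state(tab, alpha = alpha)
  n_up <- tab[["up_enr"]] + tab[["up_non"]]
  n_down <- tab[["down_enr"]] + tab[["down_non"]]
  tibble::tibble(
    up_enr = tab[["up_enr"]], up_non = tab[["up_non"]],
    down_enr = tab[["down_enr"]], down_non = tab[["down_non"]],
    p_perturbed_enr = hyper(perturbed),
    p_up_enr = hyper(up),
    p_down_enr = hyper(down),
    ud_ratio_enr = if (tab[["down_enr"]] > 0) tab[["up_enr"]] / tab[["down_enr"]] else NA_real_,
    ud_ratio_non = if (tab[["down_non"]] > 0) tab[["up_non"]] / tab[["down_non"]] else NA_real_,
    ratio_of_ratios = st$ratio_of_ratios,
    chi2_yates = st$chi2,
    chi2_p = st$p_value,
    state_call = st$call,
    regulator_call = classify_regulator(n_up, n_down, fold = fold)
  )
}
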