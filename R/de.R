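# Negative-binomial differential-expression engine for knock-down vs
# scrambled-control count matrices: TMM normalization, method-of-moments
# dispersion with shrinkage, and a conditional NB exact test.

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each library against a reference library,
#' per-gene log2 expression ratios (M) are trimmed at the extremes of M and of
#' average log expression (A), then combined as a precision-weighted mean.
#' Genes with a zero count in either library of a pair are excluded pairwise.
#' Factors are scaled so their geometric mean is 1; a pure depth difference
#' between libraries therefore yields factors of 1.
#'
#' @param counts Non-negative integer matrix (features x libraries, >= 2
#'   libraries).
#' @param lib_sizes Library sizes (default: column sums).
#' @param ref_column Reference library; by default the library whose 75th
#'   count-fraction percentile is closest to the across-library mean.
#' @param trim_M Fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_A Fraction of A-values trimmed from each tail (default 0.05).
#'
#' @return Numeric vector of normalization factors, one per library.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts), ref_column = NULL,
                        trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) abort_arg("TMM needs at least 2 libraries")
  if (any(counts < 0)) abort_arg("counts must be non-negative")
  zero_lib <- which(lib_sizes <= 0 | colSums(counts) == 0)
  if (length(zero_lib)) {
    abort_data(sprintf("library %d has no counts", zero_lib[1L]))
  }
  if (is.null(ref_column)) {
    f75 <- apply(sweep(counts, 2L, lib_sizes, "/"), 2L, stats::quantile, probs = 0.75)
    ref_column <- which.min(abs(f75 - mean(f75)))
  }
  ref <- counts[, ref_column]
  n_ref <- lib_sizes[ref_column]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    n_obs <- lib_sizes[j]
    keep0 <- obs > 0 & ref > 0
    if (!any(keep0)) return(1)
    o <- obs[keep0]; r <- ref[keep0]
    M <- log2((o / n_obs) / (r / n_ref))
    A <- (log2(o / n_obs) + log2(r / n_ref)) / 2
    v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    lo_m <- floor(n * trim_M) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_A) + 1
    hi_a <- n + 1 - lo_a
    rm <- rank(M); ra <- rank(A)
    keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep)) return(1)
    fj <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(fj)) fj <- 0
    2^fj
  }, numeric(1))
  f / gm_mean(f)
}

#' Estimate NB dispersion by pooled method of moments with shrinkage
#'
#' With counts adjusted to a common effective library size, the NB variance
#' model `var = mu + phi * mu^2` gives the moment identity
#' `phi = (var - mu) / mu^2`.  The common dispersion pools within-group
#' residual variance across all promoters (ratio of sums, floored at 0); the
#' tagwise dispersion shrinks each promoter's own moment estimate toward the
#' common value with prior weight `prior_n` (in residual-df units).  Promoters
#' whose moment estimate is non-positive or undefined take the common value.
#'
#' @param counts Feature x library count matrix.
#' @param groups Factor of library group labels; at least one group needs
#'   >= 2 replicates.
#' @param factors Normalization factors (default [tmm_factors()]).
#' @param lib_sizes Library sizes (default column sums).
#' @param prior_n Shrinkage prior weight (default 10).
#'
#' @return List with `common` (scalar phi) and `tagwise` (per-feature phi).
#' @export
estimate_dispersion <- function(counts, groups, factors = NULL,
                                lib_sizes = colSums(counts), prior_n = 10) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) abort_arg("`groups` must label every library")
  if (all(table(groups) < 2L)) {
    abort_arg(paste0("no group has replicates; dispersion cannot be estimated ",
                     "- supply a fixed dispersion to nb_exact_test() instead"))
  }
  factors <- factors %||% tmm_factors(counts, lib_sizes)
  eff <- lib_sizes * factors
  s_common <- gm_mean(eff)
  z <- sweep(counts, 2L, s_common / eff, "*")
  num <- den <- df <- rep(0, nrow(counts))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2L) next
    m <- rowMeans(z[, idx, drop = FALSE])
    v <- apply(z[, idx, drop = FALSE], 1L, stats::var)
    w <- ng - 1L
    num <- num + w * (v - m)
    den <- den + w * m^2
    df <- df + w
  }
  common <- max(sum(num) / sum(den), 0)
  phi_tag <- num / den
  phi_tag[!is.finite(phi_tag) | phi_tag <= 0] <- NA_real_
  tagwise <- ifelse(is.na(phi_tag), common,
                    (df * phi_tag + prior_n * common) / (df + prior_n))
  list(common = common, tagwise = tagwise)
}

# Two-sided conditional NB exact p-value for one feature.  Group sums of
# (common-size-adjusted) counts sA, sB from nA and nB libraries; under the
# null both groups share the per-library mean mu = (sA+sB)/(nA+nB), and the
# group-A sum given the total follows the ratio of NB products (binomial in
# the Poisson limit phi = 0).  The two-sided p sums all outcomes no more
# probable than the observed one.
exact_nb_pvalue <- function(s_a, s_b, n_a, n_b, phi) {
  tot <- s_a + s_b
  if (tot == 0) return(1)
  a <- 0:tot
  if (phi <= 0) {
    logp <- stats::dbinom(a, tot, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu <- tot / (n_a + n_b)
    r <- 1 / phi
    logp <- stats::dnbinom(a, size = n_a * r, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(tot - a, size = n_b * r, mu = n_b * mu, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[s_a + 1L] * (1 + 1e-10)]))
}

#' Conditional NB exact test per promoter
#'
#' Libraries are first adjusted to a common effective size (the geometric
#' mean of `lib_sizes * factors`); adjusted counts are then summed per group
#' and the two-sided exact p-value of the group split is computed from the
#' conditional NB distribution of the first-group sum given the total (see
#' Details).  `logFC` is the log2 ratio of normalized group means with a
#' pseudo-count of 0.5 (on the common scale) per group, so fold changes stay
#' finite at zero counts.
#'
#' @param counts Feature x library count matrix.
#' @param groups Factor with exactly two levels; `logFC` is the second level
#'   over the first (order the levels as `c(control, kd)` for knock-down
#'   over control).
#' @param dispersion Scalar or per-feature NB dispersion phi (>= 0; 0 gives
#'   the exact Poisson/binomial test).
#' @param factors Normalization factors (default [tmm_factors()]).
#' @param lib_sizes Library sizes (default column sums).
#'
#' @return Tibble `promoter`, `mean_expr` (normalized mean count), `logFC`,
#'   `p_value`, `q_value` (Benjamini-Hochberg).
#' @export
nb_exact_test <- function(counts, groups, dispersion, factors = NULL,
                          lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) abort_arg("`groups` must have exactly two levels")
  if (any(dispersion < 0)) abort_arg("`dispersion` must be >= 0")
  if (any(lib_sizes <= 0)) abort_arg("effective library sizes must be positive")
  factors <- factors %||% tmm_factors(counts, lib_sizes)
  eff <- lib_sizes * factors
  s_common <- gm_mean(eff)
  z <- sweep(counts, 2L, s_common / eff, "*")
  g1 <- groups == levels(groups)[1L]   # reference (e.g. control)
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  s1 <- unname(round(rowSums(z[, g1, drop = FALSE])))
  s2 <- unname(round(rowSums(z[, g2, drop = FALSE])))
  phi <- rep_len(dispersion, nrow(counts))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    exact_nb_pvalue(s2[i], s1[i], n2, n1, phi[i])
  }, numeric(1))
  logfc <- log2(((s2 + 0.5) / n2) / ((s1 + 0.5) / n1))
  ids <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  tibble::tibble(
    promoter = ids,
    mean_expr = (s1 + s2) / (n1 + n2),
    logFC = logfc,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH")
  )
}

#' Classify promoters as up-, down-regulated or unaffected
#'
#' A promoter is `up` if significant (`p < alpha`, or `q < alpha` with
#' `use_fdr = TRUE`) with positive `logFC` at least `log2(min_fold)`, `down`
#' symmetrically, `unaffected` otherwise.
#'
#' @param de DE table from [nb_exact_test()].
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param min_fold Additional fold-change filter (default 1, i.e. none).
#' @param use_fdr Apply `alpha` to BH q-values instead of raw p-values.
#'
#' @return `de` with a `direction` column added.
#' @export
call_de <- function(de, alpha = 0.05, min_fold = 1, use_fdr = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) abort_arg("`alpha` must be in (0, 1]")
  assert_scalar_number(min_fold, "min_fold", min = 1)
  pv <- if (use_fdr) de$q_value else de$p_value
  lfc <- log2(min_fold)
  de$direction <- dplyr::case_when(
    pv < alpha & de$logFC > 0 & de$logFC >= lfc ~ "up",
    pv < alpha & de$logFC < 0 & de$logFC <= -lfc ~ "down",
    TRUE ~ "unaffected"
  )
  de
}

#' Promoter id sets by direction
#'
#' @param de DE table with a `direction` column (see [call_de()]).
#' @return List of character vectors `up`, `down`, `unaffected`.
#' @export
de_sets <- function(de) {
  if (!"direction" %in% names(de)) abort_arg("`de` has no direction column; run call_de() first")
  list(up = de$promoter[de$direction == "up"],
       down = de$promoter[de$direction == "down"],
       unaffected = de$promoter[de$direction == "unaffected"])
}

#' Full DE analysis of one knock-down experiment
#'
#' Drops promoters with zero counts in every library (their number is
#' recorded in the `n_dropped` attribute), computes TMM factors, estimates
#' dispersion, runs the exact test and classifies directions.
#'
#' @inheritParams nb_exact_test
#' @inheritParams call_de
#' @param prior_n Dispersion shrinkage weight (see [estimate_dispersion()]).
#' @param dispersion Optional fixed dispersion; by default estimated tagwise.
#'
#' @return DE tibble with `direction`, plus attributes `n_dropped`,
#'   `dispersion_common` and `factors`.
#' @export
de_analysis <- function(counts, groups, alpha = 0.05, min_fold = 1,
                        use_fdr = FALSE, prior_n = 10, dispersion = NULL,
                        lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  n_dropped <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  factors <- tmm_factors(counts, lib_sizes)
  if (is.null(dispersion)) {
    disp <- estimate_dispersion(counts, groups, factors, lib_sizes, prior_n = prior_n)
    phi <- disp$tagwise
    common <- disp$common
  } else {
    phi <- dispersion
    common <- mean(dispersion)
  }
  de <- nb_exact_test(counts, groups, phi, factors, lib_sizes)
  de <- call_de(de, alpha = alpha, min_fold = min_fold, use_fdr = use_fdr)
  attr(de, "n_dropped") <- n_dropped
  attr(de, "dispersion_common") <- common
  attr(de, "factors") <- factors
  de
}
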