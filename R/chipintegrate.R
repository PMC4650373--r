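# Integration of ChIP-seq peak positions with knock-down DE results:
# replicate consistency, co-binding, chromatin-class overlap, distance-binned
# response, direct-target calling and core TF-TF network extraction.
#
# Peaks and annotation intervals use BED conventions throughout: 0-based,
# half-open [start, end).  GRanges (1-based, closed) is used internally for
# overlap machinery.

# BED-style tibble -> GRanges.
peaks_to_gr <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

peak_midpoint <- function(peaks) floor((peaks$start + peaks$end) / 2)

#' Replicate-consistent peaks
#'
#' A simple reproducibility filter: peaks of `rep1` are kept when they
#' overlap a `rep2` peak by at least `min_overlap` bases; each kept peak is
#' reported as the interval spanning it and all its overlapping `rep2` peaks
#' (merged interval).  Chromosomes present in only one replicate trigger a
#' warning and are dropped.
#'
#' @param rep1,rep2 Peak tibbles (`chrom`, `start`, `end`, ...), both
#'   non-empty.
#' @param min_overlap Minimum overlap in bp (default 1).
#'
#' @return Tibble of merged reproducible peaks with `rep1`'s columns.
#' @export
reproducible_peaks <- function(rep1, rep2, min_overlap = 1) {
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) abort_arg("both replicates must be non-empty")
  shared <- intersect(unique(rep1$chrom), unique(rep2$chrom))
  only <- setdiff(union(unique(rep1$chrom), unique(rep2$chrom)), shared)
  if (length(only)) {
    rlang::warn(paste0("chromosomes present in only one replicate dropped: ",
                       paste(only, collapse = ", ")))
  }
  r1 <- rep1[rep1$chrom %in% shared, , drop = FALSE]
  r2 <- rep2[rep2$chrom %in% shared, , drop = FALSE]
  if (nrow(r1) == 0L || nrow(r2) == 0L) return(r1[0, ])
  hits <- GenomicRanges::findOverlaps(peaks_to_gr(r1), peaks_to_gr(r2),
                                      minoverlap = min_overlap)
  if (length(hits) == 0L) return(r1[0, ])
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keep <- sort(unique(q))
  out <- r1[keep, , drop = FALSE]
  out$start <- vapply(keep, function(i) {
    min(r1$start[i], r2$start[s[q == i]])
  }, numeric(1)) |> as.integer()
  out$end <- vapply(keep, function(i) {
    max(r1$end[i], r2$end[s[q == i]])
  }, numeric(1)) |> as.integer()
  tibble::as_tibble(out)
}

#' Pairwise and k-way peak co-binding counts
#'
#' For every pair (and, optionally, every larger subset) of TFs, counts how
#' many peaks of each member overlap (by >= 1 bp) at least one peak of every
#' other member.  Counts are reported from each member's side (the counts
#' need not be symmetric in peak numbers).
#'
#' @param peaksets Named list (>= 2 TFs) of peak tibbles.
#' @param max_order Largest subset size to report (default: all TFs).
#'
#' @return List with `pairwise` (matrix: entry `[i, j]` = peaks of `i`
#'   overlapping `j`; diagonal = peak counts) and `subsets` (tibble `subset`,
#'   `tf`, `count` for subsets of size >= 2).
#' @export
cobinding <- function(peaksets, max_order = length(peaksets)) {
  if (length(peaksets) < 2L || is.null(names(peaksets))) {
    abort_arg("`peaksets` must be a named list of at least 2 peak sets")
  }
  grs <- lapply(peaksets, peaks_to_gr)
  tfs <- names(peaksets)
  overlaps_any <- function(a, b) {
    IRanges::overlapsAny(grs[[a]], grs[[b]], minoverlap = 1L)
  }
  pw <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (i in tfs) for (j in tfs) {
    pw[i, j] <- if (i == j) length(grs[[i]]) else sum(overlaps_any(i, j))
  }
  subs <- list()
  for (k in 2:min(max_order, length(tfs))) {
    for (set in utils::combn(tfs, k, simplify = FALSE)) {
      for (m in set) {
        others <- setdiff(set, m)
        hit <- Reduce(`&`, lapply(others, function(o) overlaps_any(m, o)))
        subs[[length(subs) + 1L]] <- tibble::tibble(
          subset = paste(set, collapse = "+"), tf = m, count = sum(hit))
      }
    }
  }
  list(pairwise = pw, subsets = dplyr::bind_rows(subs))
}

#' Peak overlap with chromatin-class annotation
#'
#' Assigns each peak midpoint to the chromatin-class interval containing it
#' (first by sorted order on ties, with a warning).  For each class the
#' observed peak count is compared with the count expected if peaks fell into
#' classes in proportion to class base-pair share, via a two-sided binomial
#' test among the peaks that hit any class interval.
#'
#' @param peaks Peak tibble.
#' @param classes Interval tibble `chrom`, `start`, `end`, `class` (0-based
#'   half-open).
#'
#' @return List with `per_class` (tibble `class`, `observed`, `expected`,
#'   `fold`, `p_value`) and `fraction_in_open` (peaks hitting any class /
#'   total peaks).
#' @export
class_overlap <- function(peaks, classes) {
  if (!all(c("chrom", "start", "end", "class") %in% names(classes))) {
    abort_arg("`classes` needs columns chrom, start, end, class")
  }
  classes <- dplyr::arrange(tibble::as_tibble(classes), .data$chrom, .data$start, .data$end)
  mids <- tibble::tibble(chrom = peaks$chrom, pos = peak_midpoint(peaks))
  mid_gr <- GenomicRanges::GRanges(mids$chrom, IRanges::IRanges(mids$pos + 1L, mids$pos + 1L))
  cls_gr <- peaks_to_gr(classes)
  hits <- GenomicRanges::findOverlaps(mid_gr, cls_gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(q)) {
    dup <- q[duplicated(q)]
    amb <- tapply(classes$class[s[q %in% dup]], q[q %in% dup],
                  function(x) length(unique(x)) > 1L)
    if (any(amb)) rlang::warn("overlapping class intervals with different labels; midpoint assigned to first by sorted order")
    first <- !duplicated(q)
    q <- q[first]; s <- s[first]
  }
  assigned <- classes$class[s]
  n_open <- length(q)
  share <- tapply(as.numeric(classes$end - classes$start), classes$class, sum)
  share <- share / sum(share)
  lvls <- sort(unique(classes$class))
  per <- lapply(lvls, function(cl) {
    obs <- sum(assigned == cl)
    expd <- n_open * share[[cl]]
    pv <- if (n_open > 0) stats::binom.test(obs, n_open, share[[cl]])$p.value else NA_real_
    tibble::tibble(class = cl, observed = obs, expected = expd,
                   fold = if (expd > 0) obs / expd else NA_real_, p_value = pv)
  })
  list(per_class = dplyr::bind_rows(per),
       fraction_in_open = n_open / max(nrow(peaks), 1L))
}

#' Distance from each promoter to its nearest peak
#'
#' The distance is `|peak midpoint - TSS position|`, minimized over the
#' peaks; strand is ignored for the distance itself but the signed distance
#' (midpoint minus TSS, genome orientation) of the nearest peak is reported
#' for diagnostics.  Promoters on chromosomes without peaks get distance
#' `Inf`.
#'
#' @param peaks Peak tibble (one TF's peaks).
#' @param tss TSS annotation tibble (`promoter`, `chrom`, `pos`, `gene`, ...).
#'
#' @return Tibble `promoter`, `gene`, `distance`, `signed_distance`,
#'   `nearest_peak` (name or index).
#' @export
peak_tss_distances <- function(peaks, tss) {
  mids <- peak_midpoint(peaks)
  nm <- if ("name" %in% names(peaks)) peaks$name else as.character(seq_len(nrow(peaks)))
  out <- tss[, c("promoter", "chrom", "pos", intersect("gene", names(tss)))]
  out$distance <- Inf
  out$signed_distance <- NA_real_
  out$nearest_peak <- NA_character_
  for (ch in unique(tss$chrom)) {
    pi <- which(peaks$chrom == ch)
    ti <- which(out$chrom == ch)
    if (!length(pi) || !length(ti)) next
    m <- mids[pi]
    ord <- order(m)
    m_sorted <- m[ord]
    pos <- out$pos[ti]
    right <- findInterval(pos, m_sorted)
    left_i <- pmax(right, 1L)
    right_i <- pmin(right + 1L, length(m_sorted))
    d_left <- abs(pos - m_sorted[left_i])
    d_right <- abs(pos - m_sorted[right_i])
    use_left <- right >= 1L & (right >= length(m_sorted) | d_left <= d_right)
    best <- ifelse(use_left, left_i, right_i)
    out$distance[ti] <- abs(pos - m_sorted[best])
    out$signed_distance[ti] <- m_sorted[best] - pos
    out$nearest_peak[ti] <- nm[pi][ord][best]
  }
  out$chrom <- NULL
  out$pos <- NULL
  tibble::as_tibble(out)
}

#' Fractions of up/down/unaffected promoters by peak distance
#'
#' Joins a classified DE table (see [call_de()]) with peak-to-TSS distances
#' and reports, per left-closed right-open distance bin, the fraction of
#' promoters in each direction.  Fractions in a non-empty bin sum to 1;
#' empty bins report `NA` fractions.
#'
#' @param de DE tibble with `direction`.
#' @param distances Distance tibble from [peak_tss_distances()].
#' @param bins Strictly increasing bin edges in bp (default
#'   `c(0, 1e3, 5e3, 1e5, Inf)`); promoters with no peak (distance `Inf`)
#'   fall in the last bin.
#'
#' @return Tibble `bin`, `n`, `n_up`, `n_down`, `frac_up`, `frac_down`,
#'   `frac_unaffected`.
#' @export
bin_response <- function(de, distances, bins = c(0, 1e3, 5e3, 1e5, Inf)) {
  if (is.unsorted(bins, strictly = TRUE)) abort_arg("`bins` must be strictly increasing")
  dat <- dplyr::inner_join(de[, c("promoter", "direction")],
                           distances[, c("promoter", "distance")],
                           by = "promoter")
  d <- pmin(dat$distance, max(bins[is.finite(bins)]) + 1)
  labels <- paste0("[", utils::head(bins, -1L), ",", utils::tail(bins, -1L), ")")
  dat$bin <- cut(d, breaks = bins, right = FALSE, labels = labels,
                 include.lowest = is.infinite(bins[length(bins)]))
  res <- lapply(labels, function(b) {
    sub <- dat[!is.na(dat$bin) & dat$bin == b, ]
    n <- nrow(sub)
    if (n == 0L) {
      return(tibble::tibble(bin = b, n = 0L, n_up = 0L, n_down = 0L,
                            frac_up = NA_real_, frac_down = NA_real_,
                            frac_unaffected = NA_real_))
    }
    nu <- sum(sub$direction == "up"); nd <- sum(sub$direction == "down")
    tibble::tibble(bin = b, n = n, n_up = nu, n_down = nd,
                   frac_up = nu / n, frac_down = nd / n,
                   frac_unaffected = (n - nu - nd) / n)
  })
  dplyr::bind_rows(res)
}

#' Call likely direct targets of a TF
#'
#' A promoter is a likely direct target when it is significantly
#' down-regulated at least `min_fold`-fold in the TF's knock-down
#' (`p < alpha`, `logFC <= -log2(min_fold)`) and lies within `max_dist` of a
#' ChIP-seq peak of the same TF (peak midpoint to TSS).
#'
#' @param de DE tibble for the TF's knock-down (needs `logFC`, `p_value`).
#' @param distances Distance tibble from [peak_tss_distances()] for the same
#'   TF's peaks.
#' @param tf TF id recorded on the output edges.
#' @param max_dist Maximum peak-to-TSS distance in bp (default 50000).
#' @param min_fold Minimum down-regulation fold (default 1.5).
#' @param alpha Significance threshold (default 0.05).
#'
#' @return Tibble of direct edges: `tf`, `promoter`, `gene`, `logFC`,
#'   `p_value`, `nearest_peak`, `distance`.
#' @export
call_direct_targets <- function(de, distances, tf = "TF", max_dist = 5e4,
                                min_fold = 1.5, alpha = 0.05) {
  assert_scalar_number(max_dist, "max_dist", min = 0, strict_min = TRUE)
  assert_scalar_number(min_fold, "min_fold", min = 1)
  assert_scalar_number(alpha, "alpha", min = 0, strict_min = TRUE)
  dat <- dplyr::inner_join(de, distances, by = "promoter")
  hit <- dat$p_value < alpha & dat$logFC <= -log2(min_fold) & dat$distance < max_dist
  out <- dat[hit, , drop = FALSE]
  if (!"gene" %in% names(out)) out$gene <- out$promoter
  tibble::tibble(tf = tf, promoter = out$promoter, gene = out$gene,
                 logFC = out$logFC, p_value = out$p_value,
                 nearest_peak = out$nearest_peak, distance = out$distance)
}

#' Extract the core TF-TF network from direct edges
#'
#' Restricts direct edges to those whose target gene is itself a
#' cell-type-enriched TF.  Gene-level semantics: a TF gene counts as a direct
#' target when any of its promoters yields a direct edge; per (source,
#' target) pair the promoter with the smallest p-value is reported.  All core
#' edges carry sign `activation` since direct calling requires down-regulation
#' on knock-down.
#'
#' @param direct_edges Direct-edge tibble (possibly several TFs bound
#'   together) from [call_direct_targets()].
#' @param enriched_tfs Character vector of enriched TF gene symbols.
#'
#' @return Tibble `source`, `target`, `sign`, `evidence`, `n_promoters`,
#'   `best_p`.
#' @export
core_trn <- function(direct_edges, enriched_tfs) {
  de <- tibble::as_tibble(direct_edges)
  de <- de[de$gene %in% enriched_tfs, , drop = FALSE]
  if (nrow(de) == 0L) {
    return(tibble::tibble(source = character(), target = character(),
                          sign = character(), evidence = character(),
                          n_promoters = integer(), best_p = numeric()))
  }
  de |>
    dplyr::group_by(source = .data$tf, target = .data$gene) |>
    dplyr::summarise(sign = "activation", evidence = "direct",
                     n_promoters = dplyr::n(),
                     best_p = min(.data$p_value), .groups = "drop") |>
    dplyr::arrange(.data$source, .data$target)
}
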