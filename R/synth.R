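# Seeded synthetic-data generators.  These plant a known regulatory network
# (the "truth") and emit the post-quantification matrices the analysis
# consumes: an expression panel, knock-down count matrices, qRT-PCR fold
# changes, TSS annotation and ChIP-seq peak sets.

#' Planted ground-truth regulatory network
#'
#' @param edges Data frame with one row per TF-target edge and columns
#'   `tf`, `target` (promoter id), `effect` (planted log2 fold change of the
#'   target in the TF knock-down; non-zero) and `direct` (logical: does the
#'   edge act through a binding site near the target TSS).  A `sign` column
#'   (+1 = up on knock-down, i.e. the TF represses; -1 = down, the TF
#'   activates) is derived from the sign of `effect`.  An optional
#'   `peak_dist` column fixes the planted peak distance (bp) for direct edges.
#' @param enriched_targets Character vector of promoter ids designated
#'   cell-type-enriched.
#'
#' @return An object of class `truth_network` with elements `edges` and
#'   `enriched_targets`.
#' @export
truth_network <- function(edges, enriched_targets = character()) {
  edges <- tibble::as_tibble(edges)
  need <- c("tf", "target", "effect", "direct")
  miss <- setdiff(need, names(edges))
  if (length(miss)) abort_arg(paste0("`edges` is missing column(s): ", paste(miss, collapse = ", ")))
  if (any(edges$effect == 0)) abort_arg("every edge must have a non-zero effect size")
  if (anyDuplicated(edges[, c("tf", "target")])) abort_arg("duplicate (tf, target) pairs in `edges`")
  edges$sign <- ifelse(edges$effect > 0, 1L, -1L)
  structure(list(edges = edges,
                 enriched_targets = unique(as.character(enriched_targets))),
            class = "truth_network")
}

#' @export
print.truth_network <- function(x, ...) {
  cat(sprintf("<truth_network> %d edges (%d direct) from %d TFs; %d enriched targets\n",
              nrow(x$edges), sum(x$edges$direct),
              length(unique(x$edges$tf)), length(x$enriched_targets)))
  invisible(x)
}

#' Generate a synthetic expression panel with planted enriched genes
#'
#' Background expression follows a shared log-normal baseline per gene
#' (meanlog 3, sdlog 1 in TPM-like units) with mild log-normal sample noise.
#' The designated enriched genes have their focal-sample value set to at
#' least `enrichment_fold` times their pseudocounted median across the other
#' samples, so the planted set is recoverable by construction.
#'
#' @param n_genes,n_samples Panel dimensions (the focal sample is one of the
#'   `n_samples` columns).
#' @param n_enriched Number of genes planted as focal-enriched
#'   (`< n_genes`).
#' @param enrichment_fold Planted fold enrichment over the panel median
#'   (> 1).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param ids,enriched_ids,tf_ids Optional explicit row ids, enriched ids and
#'   TF ids (defaults: generated ids, random enriched subset, random ~15% TF
#'   subset always covering the enriched genes plus background TFs).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param noise_sdlog Per-sample log-normal noise (sdlog).
#' @param focal_sample Name of the focal column.
#'
#' @return A list with `panel` (an [expression_panel()]) and
#'   `enriched_genes` (the planted enriched ids).
#' @export
generate_panel <- function(n_genes, n_samples, n_enriched, enrichment_fold,
                           seed, ids = NULL, enriched_ids = NULL, tf_ids = NULL,
                           baseline_meanlog = 3, baseline_sdlog = 1,
                           noise_sdlog = 0.25, focal_sample = "focal") {
  n_genes <- assert_count(n_genes, "n_genes")
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  n_enriched <- assert_count(n_enriched, "n_enriched", min = 0L)
  assert_scalar_number(enrichment_fold, "enrichment_fold", min = 1, strict_min = TRUE)
  if (n_enriched >= n_genes) abort_arg("`n_enriched` must be < `n_genes`")

  withr::with_seed(seed, {
    if (is.null(ids)) ids <- sprintf("p%04d", seq_len(n_genes))
    if (length(ids) != n_genes || anyDuplicated(ids)) {
      abort_arg("`ids` must be `n_genes` unique ids")
    }
    if (is.null(enriched_ids)) enriched_ids <- sample(ids, n_enriched)
    if (is.null(tf_ids)) {
      n_tf <- max(ceiling(0.15 * n_genes), min(n_genes, 1L))
      tf_ids <- unique(c(sample(ids, n_tf)))
    }
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    tpm <- base * matrix(stats::rlnorm(n_genes * n_samples, 0, noise_sdlog),
                         nrow = n_genes)
    rownames(tpm) <- ids
    colnames(tpm) <- c(focal_sample, sprintf("s%03d", seq_len(n_samples - 1L)))
    idx <- match(enriched_ids, ids)
    if (anyNA(idx)) abort_arg("`enriched_ids` must be a subset of `ids`")
    if (length(idx)) {
      med_other <- apply(tpm[idx, -1L, drop = FALSE], 1L, stats::median)
      uplift <- stats::runif(length(idx), 1, 1.5)
      # (x + 1)/(m + 1) >= enrichment_fold by construction, hence also x/m >=
      # enrichment_fold, so the planted genes clear both ratio conventions.
      tpm[idx, 1L] <- (enrichment_fold * (med_other + 1) - 1) * uplift
    }
    meta <- tibble::tibble(id = ids, symbol = toupper(ids), is_tf = ids %in% tf_ids)
    list(panel = expression_panel(tpm, focal_sample, meta),
         enriched_genes = enriched_ids)
  })
}

#' Generate a synthetic TSS annotation
#'
#' Places one promoter per gene at a uniformly random position on a small
#' multi-chromosome genome.  Positions are 0-based.
#'
#' @param n_promoters Number of promoters.
#' @param seed Integer seed.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param tf_ids Promoter ids flagged as TF genes.
#'
#' @return Tibble with columns `promoter`, `chrom`, `pos`, `strand`, `gene`,
#'   `is_tf`.
#' @export
generate_tss <- function(n_promoters, seed,
                         chrom_lengths = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7, chr4 = 5e7),
                         tf_ids = character()) {
  n_promoters <- assert_count(n_promoters, "n_promoters")
  withr::with_seed(seed, {
    ids <- sprintf("p%04d", seq_len(n_promoters))
    chrom <- sample(names(chrom_lengths), n_promoters, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    pos <- floor(stats::runif(n_promoters, 0, chrom_lengths[chrom]))
    tss <- tibble::tibble(
      promoter = ids,
      chrom = chrom,
      pos = as.integer(pos),
      strand = sample(c("+", "-"), n_promoters, replace = TRUE),
      gene = toupper(ids),
      is_tf = ids %in% tf_ids
    )
    dplyr::arrange(tss, .data$chrom, .data$pos)
  })
}

#' Generate knock-down CAGE-like count matrices
#'
#' For every TF appearing in the truth network, draws a promoters x libraries
#' count matrix with `n_reps` knock-down and `n_reps` scrambled-control
#' libraries.  Counts are negative binomial with variance `mu + phi * mu^2`;
#' the knock-down mean of a planted target is its baseline mean scaled by
#' `2^effect`, non-targets share means between the two groups.  Library sizes
#' vary by `+/- lib_cv` around `lib_size` to exercise normalization.
#'
#' @param truth A [truth_network()].
#' @param promoters Character vector of all promoter ids (the count matrix
#'   rows); must cover every edge target.
#' @param n_reps Replicates per group (>= 2).
#' @param lib_size Nominal library size (tags).
#' @param dispersion NB dispersion `phi` (>= 0; 0 gives Poisson counts).
#' @param lib_cv Relative half-range of library-size variation (default 0.3).
#' @param baseline Optional per-promoter baseline abundance (recycled/named);
#'   default log-normal(3, 1).
#' @param seed Integer seed.
#'
#' @return Named list (one element per TF) of lists with `counts` (integer
#'   matrix, promoters x libraries), `groups` (factor with levels
#'   `control`, `kd`) and `lib_sizes`.
#' @export
generate_kd_counts <- function(truth, promoters, n_reps = 3, lib_size = 1e6,
                               dispersion = 0.1, lib_cv = 0.3, baseline = NULL,
                               seed = 1L) {
  stopifnot(inherits(truth, "truth_network"))
  n_reps <- assert_count(n_reps, "n_reps", min = 2L)
  assert_scalar_number(dispersion, "dispersion", min = 0)
  assert_scalar_number(lib_size, "lib_size", min = 1, strict_min = TRUE)
  missing_tgt <- setdiff(truth$edges$target, promoters)
  if (length(missing_tgt)) {
    abort_arg(paste0("edge targets absent from `promoters`: ",
                     paste(utils::head(missing_tgt, 5L), collapse = ", ")))
  }
  n <- length(promoters)
  withr::with_seed(seed, {
    if (is.null(baseline)) baseline <- stats::rlnorm(n, 3, 1)
    baseline <- rep_len(baseline, n)
    rel <- baseline / sum(baseline)
    tfs <- unique(truth$edges$tf)
    out <- lapply(tfs, function(tf) {
      eff <- rep(0, n)
      e <- truth$edges[truth$edges$tf == tf, ]
      eff[match(e$target, promoters)] <- e$effect
      sizes <- lib_size * stats::runif(2L * n_reps, 1 - lib_cv, 1 + lib_cv)
      mu <- outer(rel, sizes)                     # promoters x libraries
      mu[, seq_len(n_reps)] <- mu[, seq_len(n_reps)] * 2^eff
      cnt <- if (dispersion > 0) {
        matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow = n)
      } else {
        matrix(stats::rpois(length(mu), lambda = mu), nrow = n)
      }
      rownames(cnt) <- promoters
      colnames(cnt) <- c(sprintf("kd_%s_r%d", tf, seq_len(n_reps)),
                         sprintf("ctrl_%s_r%d", tf, seq_len(n_reps)))
      list(counts = cnt,
           groups = factor(rep(c("kd", "control"), each = n_reps),
                           levels = c("control", "kd")),
           lib_sizes = sizes)
    })
    names(out) <- tfs
    out
  })
}

# Default planted peak-to-TSS distance law: a mixture of proximal (< 1 kb)
# and distal (5-45 kb) placements.  Capped at 45 kb so that every planted
# direct edge stays inside the default 50 kb direct-target calling window.
distance_law_default <- function(n, p_proximal = 0.6) {
  proximal <- stats::runif(n) < p_proximal
  ifelse(proximal, stats::runif(n, 0, 1e3), stats::runif(n, 5e3, 4.5e4))
}

#' Generate ChIP-seq-like peak sets for the truth network
#'
#' Every direct edge receives one peak whose midpoint distance to the target
#' TSS is drawn from `distance_law` (or taken from the edge's `peak_dist`
#' column when present).  `n_decoys` additional peaks per TF are placed near
#' promoters that are not targets of that TF, modelling non-functional
#' binding.
#'
#' @param truth A [truth_network()].
#' @param tss TSS annotation as returned by [generate_tss()].
#' @param distance_law Function `n -> distances (bp)` for peak placement
#'   (default: mixture of < 1 kb proximal and 5-45 kb distal).
#' @param n_decoys Decoy peaks per TF.
#' @param peak_width Peak width in bp.
#' @param seed Integer seed.
#'
#' @return Tibble of peaks (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `tf`) in BED-like 0-based half-open coordinates.
#' @export
generate_peaks <- function(truth, tss, distance_law = distance_law_default,
                           n_decoys = 0, peak_width = 200, seed = 1L) {
  stopifnot(inherits(truth, "truth_network"))
  n_decoys <- assert_count(n_decoys, "n_decoys", min = 0L)
  direct <- truth$edges[truth$edges$direct, ]
  missing_tss <- setdiff(direct$target, tss$promoter)
  if (length(missing_tss)) {
    abort_data(paste0("no TSS record for direct-edge target(s): ",
                      paste(utils::head(missing_tss, 5L), collapse = ", ")))
  }
  half <- floor(peak_width / 2)
  withr::with_seed(seed, {
    place <- function(tf, target_ids, dists, kind) {
      i <- match(target_ids, tss$promoter)
      side <- sample(c(-1L, 1L), length(i), replace = TRUE)
      mid <- pmax(tss$pos[i] + side * round(dists), half)
      tibble::tibble(
        chrom = tss$chrom[i],
        start = as.integer(mid - half),
        end = as.integer(mid - half + peak_width),
        name = sprintf("%s_%s_%s", tf, kind, target_ids),
        score = round(stats::runif(length(i), 10, 100), 1),
        strand = ".",
        tf = tf
      )
    }
    tfs <- unique(truth$edges$tf)
    res <- lapply(tfs, function(tf) {
      e <- direct[direct$tf == tf, ]
      parts <- list()
      if (nrow(e)) {
        d <- if ("peak_dist" %in% names(e) && !all(is.na(e$peak_dist))) {
          ifelse(is.na(e$peak_dist), distance_law(nrow(e)), e$peak_dist)
        } else {
          distance_law(nrow(e))
        }
        parts$direct <- place(tf, e$target, d, "direct")
      }
      if (n_decoys > 0L) {
        pool <- setdiff(tss$promoter, truth$edges$target[truth$edges$tf == tf])
        decoy_at <- sample(pool, min(n_decoys, length(pool)))
        parts$decoy <- place(tf, decoy_at, distance_law(length(decoy_at)), "decoy")
      }
      dplyr::bind_rows(parts)
    })
    out <- dplyr::bind_rows(res)
    dplyr::arrange(out, .data$tf, .data$chrom, .data$start)
  })
}

#' Generate a matrix-RNAi qRT-PCR fold-change matrix
#'
#' Per (perturbed TF, measured target, replicate), the fold change relative to
#' scrambled control is `2^(effect + N(0, noise_sd))`, where `effect` is the
#' planted edge effect (0 for non-edges).  The self cell (a TF measured in its
#' own knock-down) reports the knock-down residual `kd_residual`.
#'
#' @param truth A [truth_network()].
#' @param tf_panel TFs perturbed (columns).
#' @param target_panel Targets measured (rows).
#' @param noise_sd Replicate noise SD in log2 units.
#' @param n_reps Replicates per cell.
#' @param kd_residual Residual expression fraction of a TF in its own
#'   knock-down (default 0.3).
#' @param seed Integer seed.
#'
#' @return Long-format tibble `target`, `tf`, `replicate`, `fold_change`.
#' @export
generate_qrtpcr <- function(truth, tf_panel, target_panel, noise_sd = 0.15,
                            n_reps = 3, kd_residual = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "truth_network"))
  n_reps <- assert_count(n_reps, "n_reps")
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(target = target_panel, tf = tf_panel,
                               replicate = seq_len(n_reps))
    key <- paste(grid$tf, grid$target)
    ekey <- paste(truth$edges$tf, truth$edges$target)
    eff <- truth$edges$effect[match(key, ekey)]
    eff[is.na(eff)] <- 0
    self <- grid$target == grid$tf
    eff[self] <- log2(kd_residual)
    grid$fold_change <- 2^(eff + stats::rnorm(nrow(grid), 0, noise_sd))
    grid
  })
}

#' Generate a complete synthetic study scenario
#'
#' Builds a coherent bundle of all inputs the pipeline consumes, with a
#' planted ground truth: a TSS annotation, an expression panel whose enriched
#' rows are the planted enriched promoters, knock-down count matrices for
#' each perturbed TF, per-TF ChIP-seq peak sets (with decoys), and a
#' matrix-RNAi fold-change table.
#'
#' The defaults mirror the study design the package targets: biological
#' triplicates against scrambled controls, NB dispersion 0.1, library sizes
#' varying +/- 30%, two ChIP-profiled activator TFs with planted direct
#' targets (|log2FC| in 1.5-2.5, peaks within 45 kb of the target TSS, decoy
#' fraction 0.2), one anti-state TF whose knock-down up-regulates enriched
#' promoters, and planted TF-TF direct edges forming a known core network.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_promoters Number of promoters (default 2000).
#' @param n_samples Panel samples (default 60).
#' @param n_enriched Enriched promoters (default 400).
#' @param n_direct Direct targets per ChIP-profiled TF (default 60).
#' @param n_indirect Indirect targets per ChIP-profiled TF (default 40).
#' @param n_tf_targets Planted TF-gene direct targets of the first and second
#'   ChIP TF (default `c(12, 4)`).
#' @param n_reps,lib_size,dispersion,lib_cv Passed to [generate_kd_counts()].
#' @param decoy_fraction Fraction of each TF's peaks that are decoys
#'   (default 0.2).
#' @param distance_law Peak distance law (see [generate_peaks()]).
#' @param effect_by_distance If `TRUE`, planted effect magnitudes decay with
#'   the planted peak distance (used to study distance-binned responses).
#'
#' @return A list with `truth`, `tss`, `panel`, `counts`, `peaks`, `qrtpcr`,
#'   `chip_tfs` and `params`.
#' @export
synth_scenario <- function(seed = 1L, n_promoters = 2000, n_samples = 60,
                           n_enriched = 400, n_direct = 60, n_indirect = 40,
                           n_tf_targets = c(12L, 4L), n_reps = 3,
                           lib_size = 1e6, dispersion = 0.1, lib_cv = 0.3,
                           decoy_fraction = 0.2,
                           distance_law = distance_law_default,
                           effect_by_distance = FALSE) {
  withr::with_seed(seed, {
    ids <- sprintf("p%04d", seq_len(n_promoters))
    # TF genes: the perturbed TFs plus a pool of candidate TF targets.
    tf_gene_pool <- sample(ids, 60L)
    chip_tfs <- c("TF1", "TF2")
    anti_tf <- "TF3"

    pick <- function(pool, n) sample(pool, n)
    used <- character()
    edges <- list()
    tf_targets <- list()
    for (k in seq_along(chip_tfs)) {
      tf <- chip_tfs[k]
      tft <- pick(setdiff(tf_gene_pool, used), n_tf_targets[k])
      dt <- pick(setdiff(ids, c(used, tft)), n_direct - length(tft))
      it <- pick(setdiff(ids, c(used, tft, dt)), n_indirect)
      used <- c(used, tft, dt, it)
      tf_targets[[tf]] <- tft
      dist <- distance_law(length(tft) + length(dt))
      eff_mag <- if (effect_by_distance) {
        2.5 - 1.6 * pmin(dist, 1e5) / 1e5
      } else {
        stats::runif(length(dist), 1.5, 2.5)
      }
      edges[[length(edges) + 1L]] <- tibble::tibble(
        tf = tf, target = c(tft, dt), effect = -eff_mag,
        direct = TRUE, peak_dist = round(dist)
      )
      edges[[length(edges) + 1L]] <- tibble::tibble(
        tf = tf, target = it,
        effect = sample(c(-1, 1), length(it), replace = TRUE) *
          stats::runif(length(it), 1.5, 2.5),
        direct = FALSE, peak_dist = NA_real_
      )
    }
    # Anti-state TF: up-regulates enriched promoters on knock-down, no ChIP.
    anti_targets <- pick(setdiff(ids, used), 50L)
    used <- c(used, anti_targets)
    edges[[length(edges) + 1L]] <- tibble::tibble(
      tf = anti_tf, target = anti_targets,
      effect = stats::runif(50L, 1.5, 2.5), direct = FALSE, peak_dist = NA_real_
    )
    edges <- dplyr::bind_rows(edges)

    # Enriched set: all targets of the ChIP TFs and the anti TF, padded with
    # random background promoters up to n_enriched.
    core_enriched <- unique(c(edges$target[edges$tf %in% chip_tfs & edges$effect < 0],
                              anti_targets, unlist(tf_targets)))
    pad <- pick(setdiff(ids, core_enriched), max(0L, n_enriched - length(core_enriched)))
    enriched <- c(core_enriched, pad)
    truth <- truth_network(edges, enriched_targets = enriched)

    tss <- generate_tss(n_promoters, seed = seed + 11L,
                        tf_ids = unique(c(tf_gene_pool, character())))
    pan <- generate_panel(n_promoters, n_samples, length(enriched),
                          enrichment_fold = 8, seed = seed + 23L,
                          ids = ids, enriched_ids = enriched,
                          tf_ids = tf_gene_pool)
    counts <- generate_kd_counts(truth, ids, n_reps = n_reps,
                                 lib_size = lib_size, dispersion = dispersion,
                                 lib_cv = lib_cv, seed = seed + 37L)
    n_decoys <- round(decoy_fraction / (1 - decoy_fraction) * n_direct)
    peaks <- generate_peaks(truth, tss, distance_law = distance_law,
                            n_decoys = n_decoys, seed = seed + 53L)
    qpcr_tfs <- c(chip_tfs, anti_tf)
    qpcr_targets <- unique(c(sample(unique(edges$target), 40L), qpcr_tfs))
    qrtpcr <- generate_qrtpcr(truth, qpcr_tfs, qpcr_targets, seed = seed + 71L)

    list(truth = truth, tss = tss, panel = pan$panel, counts = counts,
         peaks = peaks, qrtpcr = qrtpcr, chip_tfs = chip_tfs,
         tf_targets = tf_targets,
         params = list(seed = seed, n_promoters = n_promoters,
                       n_reps = n_reps, lib_size = lib_size,
                       dispersion = dispersion, decoy_fraction = decoy_fraction))
  })
}
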