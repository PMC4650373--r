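# End-to-end pipeline on a synthetic scenario: generate -> rank ->
# matrix-RNAi -> DE -> state -> integrate -> core TRN.

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Generates the scenario from the configuration seed, then runs every
#' analysis stage: TF enrichment ranking, enriched-promoter set, matrix-RNAi
#' edge calling, per-TF differential expression, per-TF state tables,
#' peak-to-TSS distances, distance-binned responses, direct-target calling
#' and core TF-TF network extraction.  Deterministic given the configuration
#' (identical configs give identical bundles).  When `outdir` is given every
#' stage output is written as a TSV with a metadata header recording package
#' version, seed and config hash.
#'
#' @param config A [trn_config()].
#' @param outdir Optional output directory.
#' @param scenario Optional pre-built scenario (from [synth_scenario()]);
#'   by default built from `config`.
#'
#' @return A list bundle: `scenario`, `ranking`, `enriched`, `rnai_edges`,
#'   `degrees`, `kd_efficiency`, `de` (per TF), `state` (per TF),
#'   `distances` (per ChIP TF), `bins` (per ChIP TF), `direct_edges`,
#'   `core` and `config`.
#' @export
run_pipeline <- function(config = trn_config(), outdir = NULL, scenario = NULL) {
  stopifnot(inherits(config, "trn_config"))
  scen <- scenario %||% do.call(synth_scenario,
                                c(list(seed = config$seed), config$synth))

  ranking <- rank_tfs(scen$panel)
  enriched <- enriched_promoters(scen$panel, fold_threshold = config$promoter_fold)

  rnai_edges <- call_edges(scen$qrtpcr, threshold = config$edge_fold)
  degrees <- degree_summary(rnai_edges, tfs = unique(scen$qrtpcr$tf))
  kd_eff <- kd_efficiency(scen$qrtpcr)

  de <- lapply(scen$counts, function(x) {
    de_analysis(x$counts, x$groups, alpha = config$de_alpha)
  })

  state <- lapply(names(de), function(tf) {
    s <- de_sets(de[[tf]])
    state_table(s$up, s$down, enriched, de[[tf]]$promoter,
                alpha = config$de_alpha)
  })
  names(state) <- names(de)
  state <- dplyr::bind_rows(state, .id = "tf")

  chip <- intersect(scen$chip_tfs, names(de))
  distances <- lapply(chip, function(tf) {
    peak_tss_distances(scen$peaks[scen$peaks$tf == tf, ], scen$tss)
  })
  names(distances) <- chip
  bins <- lapply(chip, function(tf) {
    bin_response(de[[tf]], distances[[tf]], bins = config$bins)
  })
  names(bins) <- chip
  direct <- dplyr::bind_rows(lapply(chip, function(tf) {
    call_direct_targets(de[[tf]], distances[[tf]], tf = tf,
                        max_dist = config$max_dist,
                        min_fold = config$direct_fold,
                        alpha = config$de_alpha)
  }))
  enriched_tf_genes <- scen$tss$gene[scen$tss$is_tf & scen$tss$promoter %in% enriched]
  core <- core_trn(direct, enriched_tf_genes)

  bundle <- list(scenario = scen, ranking = ranking, enriched = enriched,
                 rnai_edges = rnai_edges, degrees = degrees,
                 kd_efficiency = kd_eff, de = de, state = state,
                 distances = distances, bins = bins, direct_edges = direct,
                 core = core, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(bundle, outdir)
  bundle
}

# Serialize the bundle stage by stage; every file carries version/seed/hash.
write_pipeline_outputs <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = bundle$config$seed,
               config_hash = rlang::hash(unclass(bundle$config)))
  w <- function(df, name) write_trn_tsv(df, file.path(outdir, name), meta = meta)
  w(bundle$ranking, "tf_ranking.tsv")
  w(tibble::tibble(promoter = bundle$enriched), "enriched_promoters.tsv")
  w(bundle$rnai_edges, "rnai_edges.tsv")
  w(bundle$degrees$out_degree, "out_degree.tsv")
  w(bundle$kd_efficiency, "kd_efficiency.tsv")
  for (tf in names(bundle$de)) {
    w(bundle$de[[tf]], sprintf("de_%s.tsv", tf))
  }
  w(bundle$state, "state_table.tsv")
  for (tf in names(bundle$bins)) {
    w(bundle$bins[[tf]], sprintf("bin_response_%s.tsv", tf))
  }
  w(bundle$direct_edges, "direct_edges.tsv")
  w(bundle$core, "core_trn.tsv")
  invisible(outdir)
}

#' Direct-edge precision and recall against planted truth
#'
#' Compares called direct edges with the planted direct edges of a truth
#' network at the (tf, promoter) level.
#'
#' @param direct_edges Tibble from [call_direct_targets()].
#' @param truth A [truth_network()].
#'
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
edge_recovery <- function(direct_edges, truth) {
  stopifnot(inherits(truth, "truth_network"))
  called <- unique(paste(direct_edges$tf, direct_edges$promoter))
  planted <- truth$edges[truth$edges$direct, ]
  truthkey <- unique(paste(planted$tf, planted$target))
  tp <- length(intersect(called, truthkey))
  fp <- length(setdiff(called, truthkey))
  fn <- length(setdiff(truthkey, called))
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
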