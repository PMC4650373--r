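# Scenario configuration: the analysis thresholds bundled with seeds, with
# lossless YAML round-tripping.

#' Build a pipeline configuration
#'
#' Collects every analysis threshold with its conventional default: TF
#' enrichment-score cutoff 1.25 (about 18-fold over the panel median),
#' promoter enrichment fold 3, DE significance 0.05, matrix-RNAi edge fold
#' 1.5, direct-target fold 1.5 within 50 kb of a peak, detection threshold
#' 5 TPM and ORA background threshold 1 TPM.
#'
#' @param seed Integer seed for the synthetic scenario.
#' @param enrichment_score TF enrichment score cutoff (log10 units).
#' @param promoter_fold Promoter enrichment fold cutoff.
#' @param de_alpha DE significance level.
#' @param edge_fold Matrix-RNAi fold-change threshold.
#' @param direct_fold Direct-target down-regulation fold.
#' @param max_dist Direct-target maximum peak distance (bp).
#' @param detection_tpm Gene-set detection threshold (TPM).
#' @param background_tpm ORA background expression threshold (TPM).
#' @param bins Distance bin edges (bp).
#' @param synth Named list of overrides passed to [synth_scenario()].
#'
#' @return A `trn_config` list.
#' @export
trn_config <- function(seed = 1L, enrichment_score = 1.25, promoter_fold = 3,
                       de_alpha = 0.05, edge_fold = 1.5, direct_fold = 1.5,
                       max_dist = 5e4, detection_tpm = 5, background_tpm = 1,
                       bins = c(0, 1e3, 5e3, 1e5, Inf), synth = list()) {
  cfg <- list(seed = as.integer(seed), enrichment_score = enrichment_score,
              promoter_fold = promoter_fold, de_alpha = de_alpha,
              edge_fold = edge_fold, direct_fold = direct_fold,
              max_dist = max_dist, detection_tpm = detection_tpm,
              background_tpm = background_tpm, bins = bins, synth = synth)
  num <- setdiff(names(cfg), c("synth", "bins", "seed"))
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      abort_arg(sprintf("threshold `%s` must be a positive number", k))
    }
  }
  structure(cfg, class = "trn_config")
}

#' Write a configuration as YAML
#'
#' @param config A [trn_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trn_config <- function(config, path) {
  x <- unclass(config)
  x$bins <- ifelse(is.infinite(x$bins), ".inf", x$bins)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' @param path YAML path.
#' @return A [trn_config()]; round-trips [write_trn_config()] losslessly.
#' @export
read_trn_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bins <- as.numeric(ifelse(x$bins == ".inf", Inf, x$bins))
  do.call(trn_config, x)
}
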