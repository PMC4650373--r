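# Generic hypergeometric over-representation analysis.

#' Over-representation analysis of a gene set against a term map
#'
#' For each annotation term, tests whether the query set contains more term
#' members than expected from the background using the upper-tail
#' hypergeometric probability ([hypergeom_tail()]; the same implementation
#' used for the state-enrichment tests), with Benjamini-Hochberg correction
#' across the tested terms.  Terms with fewer than `min_term_size` background
#' members are skipped.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param term_map Either a data frame with columns `term` and `gene`, or a
#'   named list of gene-id vectors.
#' @param background Character vector of background gene ids (e.g. all genes
#'   expressed above 1 TPM in the focal sample).
#' @param min_term_size Minimum in-background term size tested (default 3).
#'
#' @return Tibble `term`, `k` (query hits), `K` (term size in background),
#'   `n` (query size), `N` (background size), `p_value`, `q_value`, sorted by
#'   p-value.
#' @export
ora_test <- function(query, term_map, background, min_term_size = 3) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  bad <- setdiff(query, background)
  if (length(bad)) {
    abort_data(paste0("query genes absent from background: ",
                      paste(utils::head(bad, 10L), collapse = ", ")))
  }
  if (is.data.frame(term_map)) {
    if (!all(c("term", "gene") %in% names(term_map))) {
      abort_arg("`term_map` data frame needs columns term, gene")
    }
    term_map <- split(as.character(term_map$gene), term_map$term)
  }
  term_map <- lapply(term_map, function(g) unique(as.character(g)))
  n <- length(query)
  N <- length(background)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(term_map[[tm]], background)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(members, query))
    tibble::tibble(term = tm, k = k, K = K, n = n, N = N,
                   p_value = hypergeom_tail(k, K, n, N))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out$q_value <- numeric()
    return(out)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value, .data$term)
}

#' Read a term map from TSV or GMT
#'
#' TSV files need two columns (`term`, `gene`); GMT files follow the usual
#' one-term-per-line layout (term, description, genes...).
#'
#' @param path File path; format chosen by the `.gmt` extension.
#' @return Tibble with columns `term`, `gene`.
#' @export
read_term_map <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    rows <- lapply(lines[nzchar(lines)], function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) abort_data("GMT lines need term, description and >= 1 gene")
      tibble::tibble(term = f[1L], gene = f[-(1:2)])
    })
    return(dplyr::bind_rows(rows))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("term", "gene") %in% names(df))) {
    abort_data("term-map TSV needs columns term, gene")
  }
  tibble::as_tibble(df[, c("term", "gene")])
}
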