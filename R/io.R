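# Readers and writers for the plain-text interchange formats: BED intervals,
# TSV tables with '#'-prefixed metadata headers, expression panels and count
# matrices.

#' Read a BED3-BED6 file of peaks or intervals
#'
#' Coordinates are 0-based half-open, as in the BED standard.  `track`,
#' `browser` and `#` comment lines are skipped.  Malformed lines (fewer than
#' 3 fields, non-numeric or inverted coordinates) raise an error naming the
#' line number.
#'
#' @param path File path.
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (missing optional fields filled with `"."`, `0`, `"."`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  parse_line <- function(f, lineno) {
    if (length(f) < 3L) {
      abort_data(sprintf("line %d: expected at least 3 tab-separated fields", lineno))
    }
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end)) {
      abort_data(sprintf("line %d: non-numeric coordinates", lineno))
    }
    if (start >= end) {
      abort_data(sprintf("line %d: start must be < end (half-open intervals)", lineno))
    }
    score <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0
    tibble::tibble(
      chrom = f[1L], start = as.integer(start), end = as.integer(end),
      name = if (length(f) >= 4L) f[4L] else ".",
      score = if (is.na(score)) 0 else score,
      strand = if (length(f) >= 6L) f[6L] else "."
    )
  }
  if (!length(idx)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          name = character(), score = numeric(), strand = character()))
  }
  dplyr::bind_rows(Map(parse_line, fields, idx))
}

#' Write intervals as BED6
#'
#' @param peaks Tibble with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` are filled with placeholders when absent.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = peaks$chrom,
    start = format(peaks$start, scientific = FALSE, trim = TRUE),
    end = format(peaks$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(peaks)) peaks$name else ".",
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV with a '#'-prefixed metadata header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list of metadata recorded as `# key: value` lines
#'   (package version is always included).
#' @return `path`, invisibly.
#' @export
write_trn_tsv <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("trnmapr ", as.character(utils::packageVersion("trnmapr")))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_trn_tsv()]
#'
#' @param path File path.
#' @return Tibble; metadata lines are parsed into the `meta` attribute.
#' @export
read_trn_tsv <- function(path) {
  lines <- readLines(path, n = 100L)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^# ", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ?", "", kv)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Read an expression panel TSV
#'
#' Expects columns `id`, `symbol`, `is_tf`, then one numeric column per
#' sample.
#'
#' @param path File path.
#' @param focal_sample Name of the focal sample column.
#' @return An [expression_panel()].
#' @export
read_panel <- function(path, focal_sample) {
  df <- read_trn_tsv(path)
  need <- c("id", "symbol", "is_tf")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_data(paste0("panel TSV is missing column(s): ", paste(miss, collapse = ", ")))
  samples <- setdiff(names(df), need)
  tpm <- as.matrix(df[, samples])
  rownames(tpm) <- df$id
  expression_panel(tpm, focal_sample,
                   meta = df[, need])
}

#' Write an expression panel TSV
#'
#' @param panel An [expression_panel()].
#' @param path Output path.
#' @param meta Extra metadata for the header.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, meta = list()) {
  df <- cbind(panel$meta, as.data.frame(panel$tpm))
  write_trn_tsv(df, path, meta = c(list(focal_sample = panel$focal_sample), meta))
}

#' Read a count matrix with group labels
#'
#' The TSV needs a `promoter` id column and one integer column per library;
#' the group of each library is taken from `groups` (named vector or
#' two-column data frame `library`, `group`).
#'
#' @param path Count TSV path.
#' @param groups Library group labels.
#' @return List `counts` (matrix), `groups` (factor, levels with `control`
#'   first when present).
#' @export
read_counts <- function(path, groups) {
  df <- read_trn_tsv(path)
  if (!"promoter" %in% names(df)) abort_data("count TSV needs a `promoter` column")
  counts <- as.matrix(df[, setdiff(names(df), "promoter")])
  rownames(counts) <- df$promoter
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$library)
  g <- groups[colnames(counts)]
  if (anyNA(g)) abort_data("every library column needs a group label")
  lv <- unique(g)
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))
  list(counts = counts, groups = factor(g, levels = lv))
}

#' Read a TSS annotation table
#'
#' BED-like TSV with 0-based positions: columns `promoter`, `chrom`, `pos`,
#' `strand`, `gene`, `is_tf`.
#'
#' @param path File path.
#' @return Tibble of TSS records.
#' @export
read_tss <- function(path) {
  df <- read_trn_tsv(path)
  need <- c("promoter", "chrom", "pos", "strand", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_data(paste0("TSS TSV is missing column(s): ", paste(miss, collapse = ", ")))
  if (!"is_tf" %in% names(df)) df$is_tf <- FALSE
  df
}
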