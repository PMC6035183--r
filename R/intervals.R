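# BED-style interval I/O. All intervals are 0-based half-open throughout the
# package; strand is one of "+", "-", ".".

BED_KINDS <- c("tfbs", "dhs", "promoter", "blacklist", "gene", "reads", "lesion")

#' Read genomic intervals from a BED file
#'
#' Parses BED3/BED6 (plus optional extra columns) into a tibble, preserving
#' 0-based half-open coordinates and input order. `kind = "tfbs"` requires a
#' name column (the TF) and reads a `motif_class` tag (`known`/`discovered`)
#' from column 7 when present (as bare value or `motif_class=value`).
#'
#' @param path path to a tab-separated BED file (no header).
#' @param kind one of `r paste0('"', BED_KINDS, '"', collapse = ", ")`;
#'   controls required columns.
#' @param verbose log row counts.
#' @return tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (and `motif_class` for `kind = "tfbs"`).
#' @export
read_intervals <- function(path, kind = "tfbs", verbose = FALSE) {
  kind <- match.arg(kind, BED_KINDS)
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 3L) abort("BED file needs >= 3 tab-separated columns")
  ncols <- ncol(raw)
  df <- tibble(
    chrom = as.character(raw[[1]]),
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]])),
    name = if (ncols >= 4) as.character(raw[[4]]) else ".",
    score = if (ncols >= 5) suppressWarnings(as.numeric(raw[[5]])) else NA_real_,
    strand = if (ncols >= 6) as.character(raw[[6]]) else "."
  )
  if (anyNA(df$start) || anyNA(df$end)) abort("non-integer BED coordinates")
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    abort(sprintf("empty or inverted interval at line %d (start >= end)", bad[1]))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    abort(sprintf("unknown strand symbol at line %d",
                  which(!df$strand %in% c("+", "-", "."))[1]))
  }
  if (kind == "tfbs") {
    if (ncols < 4) abort("tfbs BED requires a name (TF) column")
    mc <- if (ncols >= 7) sub("^motif_class=", "", as.character(raw[[7]])) else "known"
    if (!all(mc %in% c("known", "discovered"))) {
      abort("tfbs motif_class column must be 'known' or 'discovered'")
    }
    df$motif_class <- mc
  }
  log_filter(paste0("read_intervals:", kind), nrow(df), nrow(df), verbose)
  df
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end`, `name`, `score`, `strand` as tab-separated
#' BED6 (score NA written as 0). Round-trips [read_intervals()] output
#' byte-identically for well-formed BED6.
#'
#' @param intervals tibble with at least `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  df <- tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = col_or_null(intervals, "name") %||% ".",
    score = {
      s <- col_or_null(intervals, "score") %||% 0
      ifelse(is.na(s), 0, s)
    },
    strand = col_or_null(intervals, "strand") %||% "."
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write lesion records as BED6
#'
#' Lesions are written with name = dinucleotide (5'->3' on the lesion
#' strand), score = 1 and strand = lesion strand.
#'
#' @param lesions tibble from [call_cpd()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lesions <- function(lesions, path) {
  write_intervals(
    tibble(chrom = lesions$chrom, start = lesions$start, end = lesions$end,
           name = lesions$dinuc, score = 1, strand = lesions$strand),
    path
  )
}
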