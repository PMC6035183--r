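# Somatic single-base-substitution table I/O.

#' Read a somatic mutation table
#'
#' Reads a tab-separated table with header columns `chrom`, `pos` (1-based
#' position of the mutated base), `ref`, `alt`, `donor`. Rows that are not
#' single-base substitutions (multi-base ref/alt, indel symbols, ref == alt)
#' are dropped with a logged count. If a genome is supplied, rows whose `ref`
#' does not match the genome are dropped with a logged count.
#'
#' @param path path to the TSV file.
#' @param genome optional `DNAStringSet` for reference-consistency checks.
#' @param verbose log filter counts.
#' @return tibble with columns `chrom`, `pos`, `ref`, `alt`, `donor`; the
#'   attribute `"dropped"` carries the named drop counters.
#' @export
read_mutations <- function(path, genome = NULL, verbose = FALSE) {
  if (!file.exists(path)) abort(paste0("mutation TSV not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "donor")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("mutation table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  df <- tibble(chrom = df$chrom, pos = as.integer(df$pos),
               ref = toupper(df$ref), alt = toupper(df$alt), donor = df$donor)
  n0 <- nrow(df)
  single <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  dropped <- c(not_single_base = sum(!single))
  df <- df[single, ]
  log_filter("read_mutations:single_base", n0, nrow(df), verbose)
  if (!is.null(genome)) {
    n1 <- nrow(df)
    on_chrom <- df$chrom %in% names(genome)
    len <- Biostrings::width(genome)[match(df$chrom, names(genome))]
    in_range <- on_chrom & df$pos >= 1L & df$pos <= ifelse(is.na(len), 0L, len)
    match_ref <- rep(FALSE, n1)
    if (any(in_range)) {
      match_ref[in_range] <- genome_base(genome, df$chrom[in_range],
                                         df$pos[in_range] - 1L) == df$ref[in_range]
    }
    dropped <- c(dropped, ref_mismatch = sum(!match_ref))
    df <- df[match_ref, ]
    log_filter("read_mutations:ref_match", n1, nrow(df), verbose)
  }
  attr(df, "dropped") <- dropped
  df
}

#' Write a mutation table
#'
#' @param mutations tibble with `chrom`, `pos`, `ref`, `alt`, `donor`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  readr::write_tsv(mutations[c("chrom", "pos", "ref", "alt", "donor")], path,
                   progress = FALSE)
  invisible(path)
}

#' Remove per-patient duplicate mutation calls
#'
#' Keeps one record per (chrom, pos, alt, donor), so a mutation called in
#' several tumor samples of the same patient is counted once.
#'
#' @param mutations mutation tibble.
#' @param verbose log counts.
#' @return deduplicated tibble.
#' @export
dedupe_donor_mutations <- function(mutations, verbose = FALSE) {
  n0 <- nrow(mutations)
  out <- dplyr::distinct(mutations, .data$chrom, .data$pos, .data$alt,
                         .data$donor, .keep_all = TRUE)
  log_filter("dedupe_donor_mutations", n0, nrow(out), verbose)
  out
}
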