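# Reference genome I/O and base lookup.

#' Read a reference genome from FASTA
#'
#' Loads all records of a FASTA file into a named [Biostrings::DNAStringSet],
#' upper-casing every sequence. Record names are taken as the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet` with one entry per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- read_genome(fa)
#' genome_seq(g, "chr1", 0, 4) # "ACGT"
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  names(x) <- nm
  # upper-case in place; DNAStringSet already restricts the alphabet
  Biostrings::DNAStringSet(toupper(x))
}

#' Write a genome to FASTA
#'
#' @param genome a `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

check_chrom <- function(genome, chrom) {
  bad <- setdiff(unique(chrom), names(genome))
  if (length(bad)) abort(paste0("chromosome(s) not in genome: ",
                                paste(bad, collapse = ", ")))
}

#' Extract genome sequence over 0-based half-open intervals
#'
#' @param genome a `DNAStringSet` from [read_genome()].
#' @param chrom chromosome name(s).
#' @param start,end 0-based half-open coordinates (vectorised, recycled
#'   against `chrom`).
#' @return character vector of plus-strand sequences.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  check_chrom(genome, chrom)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(start < 0 | end > len | start >= end)) {
    abort("genome_seq: interval out of range or empty")
  }
  out <- character(n)
  for (cm in unique(chrom)) {
    i <- which(chrom == cm)
    v <- Biostrings::extractAt(genome[[cm]],
                               IRanges::IRanges(start[i] + 1L, end[i]))
    out[i] <- as.character(v)
  }
  out
}

#' Look up single bases (0-based)
#'
#' @inheritParams genome_seq
#' @param pos 0-based position(s).
#' @return character vector of single bases.
#' @export
genome_base <- function(genome, chrom, pos) {
  genome_seq(genome, chrom, pos, pos + 1L)
}

#' Chromosome lengths of a genome
#'
#' @param genome a `DNAStringSet`.
#' @return tibble with columns `chrom`, `length`.
#' @export
genome_lengths <- function(genome) {
  tibble(chrom = names(genome), length = Biostrings::width(genome))
}

# Chromosome as a single upper-case character string (fast substring access).
chrom_string <- function(genome, chrom) {
  check_chrom(genome, chrom)
  as.character(genome[[chrom]])
}
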