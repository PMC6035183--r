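# CPD lesion calling from CPD-seq read ends and XR-seq lesion localization.
#
# CPD-seq chemistry cleaves immediately 3' of the dimer on the damaged
# strand, so the two bases just upstream of a read's 5' end, on the strand
# opposite the read, are the putative lesion.

#' Classify a dinucleotide as a CPD class
#'
#' @param dinuc character vector of length-2 upper-case dinucleotides.
#' @return factor-like character vector in
#'   `c("TT","TC","CT","CC","background")`; any 2-mer containing A, G or N is
#'   background.
#' @examples
#' classify_dinuc(c("TC", "TT", "GA"))
#' @export
classify_dinuc <- function(dinuc) {
  if (any(nchar(dinuc) != 2L)) abort("classify_dinuc: dinucleotides must have length 2")
  ifelse(dinuc %in% DIPYRIMIDINES, dinuc, "background")
}

#' Is a dinucleotide a mutagenic CPD class?
#'
#' mCPDs are cytosine-containing dipyrimidines (TC, CT, CC), the classes
#' whose deamination-prone cytosines drive UV mutagenesis.
#'
#' @param dinuc character vector of dinucleotides.
#' @return logical vector.
#' @export
is_mcpd <- function(dinuc) {
  dinuc %in% c("TC", "CT", "CC")
}

read_five_prime <- function(reads) {
  fp <- col_or_null(reads, "five_prime")
  if (!is.null(fp)) return(as.integer(fp))
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Call CPD lesions from mapped read 5' ends
#'
#' For a plus-strand read with 5' end at `s` the two plus-strand bases over
#' `[s-2, s)` are extracted and the lesion is their reverse complement on the
#' minus strand over the same interval. For a minus-strand read with 5' end
#' at `e` (its rightmost aligned base) the window corresponds to plus-strand
#' interval `[e+1, e+3)` and the lesion lies on the plus strand. Reads whose
#' window falls off the chromosome (`edge`), contains N (`ambiguous_base`) or
#' yields a non-dipyrimidine (`non_dipyrimidine`) are rejected and counted.
#'
#' @param reads tibble of mapped reads: `chrom`, `strand` and either a
#'   `five_prime` column (0-based coordinate of the 5'-most aligned base) or
#'   BED-style `start`/`end` from which it is derived.
#' @param genome `DNAStringSet` from [read_genome()].
#' @param verbose log filter counts.
#' @return tibble of lesions (`chrom`, `start`, `end`, `strand`, `dinuc`,
#'   `is_mCPD`) spanning exactly two bases each; attribute `"rejected"`
#'   carries named rejection counters.
#' @export
call_cpd <- function(reads, genome, verbose = FALSE) {
  if (!all(reads$strand %in% c("+", "-"))) {
    abort("call_cpd: reads must be stranded (+/-)")
  }
  check_chrom(genome, reads$chrom)
  fp <- read_five_prime(reads)
  win_start <- ifelse(reads$strand == "+", fp - 2L, fp + 1L)
  len <- Biostrings::width(genome)[match(reads$chrom, names(genome))]
  ok_edge <- win_start >= 0L & (win_start + 2L) <= len
  plus2 <- rep(NA_character_, nrow(reads))
  if (any(ok_edge)) {
    plus2[ok_edge] <- genome_seq(genome, reads$chrom[ok_edge],
                                 win_start[ok_edge], win_start[ok_edge] + 2L)
  }
  has_n <- ok_edge & grepl("N", plus2, fixed = TRUE)
  dinuc <- ifelse(reads$strand == "+", revcomp(plus2), plus2)
  is_dipy <- ok_edge & !has_n & dinuc %in% DIPYRIMIDINES
  rejected <- c(edge = sum(!ok_edge),
                ambiguous_base = sum(has_n),
                non_dipyrimidine = sum(ok_edge & !has_n & !dinuc %in% DIPYRIMIDINES))
  keep <- which(is_dipy)
  out <- tibble(
    chrom = reads$chrom[keep],
    start = as.integer(win_start[keep]),
    end = as.integer(win_start[keep] + 2L),
    strand = ifelse(reads$strand[keep] == "+", "-", "+"),
    dinuc = dinuc[keep],
    is_mCPD = is_mcpd(dinuc[keep])
  )
  log_filter("call_cpd", nrow(reads), nrow(out), verbose)
  attr(out, "rejected") <- rejected
  out
}

#' Localize the repaired lesion within XR-seq reads
#'
#' Excised oligomers released by nucleotide excision repair carry the lesion
#' at a fixed register from their 3' end. For offsets o = 6, 7, 8 (in that
#' order) the dinucleotide whose 3' base lies o bases upstream of the
#' 3'-terminal base is tested in read-strand coordinates; the first
#' dipyrimidine found is reported as the lesion, mapped to genomic
#' coordinates on the read strand. Reads with no dipyrimidine in the window
#' are rejected (`no_dipyrimidine`).
#'
#' @param reads tibble with `chrom`, `start`, `end`, `strand` (aligned span,
#'   0-based half-open).
#' @param genome `DNAStringSet`; read-strand sequences are derived from it.
#' @param offsets integer offsets searched in order (default `6:8`).
#' @param terminal_inclusive if `TRUE`, "o bases upstream" counts the
#'   3'-terminal base itself as 1, shifting the register one base toward the
#'   3' end (alternate reading of the search window).
#' @param verbose log filter counts.
#' @return tibble of lesion intervals (`chrom`, `start`, `end`, `strand`,
#'   `dinuc`, `offset`) with attribute `"rejected"`.
#' @export
localize_xrseq <- function(reads, genome, offsets = 6:8,
                           terminal_inclusive = FALSE, verbose = FALSE) {
  if (!all(reads$strand %in% c("+", "-"))) abort("localize_xrseq: reads must be stranded")
  L <- reads$end - reads$start
  if (any(L <= 10L)) abort("localize_xrseq: read length must exceed 10")
  seqs <- genome_seq(genome, reads$chrom, reads$start, reads$end)
  rs <- ifelse(reads$strand == "+", seqs, revcomp(seqs))
  n <- nrow(reads)
  hit_off <- rep(NA_integer_, n)
  hit_idx <- rep(NA_integer_, n)  # 0-based read index of the dinuc 5' base
  for (o in offsets) {
    # 3' base of the candidate dinucleotide at read index L - 1 - o
    i3 <- L - 1L - o + as.integer(terminal_inclusive)
    cand <- substr(rs, i3, i3 + 1L)  # substr is 1-based: bases i3-1, i3 (0-based)
    ok <- is.na(hit_off) & cand %in% DIPYRIMIDINES
    hit_off[ok] <- o
    hit_idx[ok] <- i3[ok] - 1L
  }
  keep <- which(!is.na(hit_off))
  rejected <- c(no_dipyrimidine = n - length(keep))
  i5 <- hit_idx[keep]  # 0-based read index of the 5' base of the dinuc
  gstart <- ifelse(reads$strand[keep] == "+",
                   reads$start[keep] + i5,
                   reads$end[keep] - 2L - i5)
  dn <- substr(rs[keep], i5 + 1L, i5 + 2L)
  out <- tibble(
    chrom = reads$chrom[keep],
    start = as.integer(gstart),
    end = as.integer(gstart + 2L),
    strand = reads$strand[keep],
    dinuc = dn,
    offset = hit_off[keep]
  )
  log_filter("localize_xrseq", n, nrow(out), verbose)
  attr(out, "rejected") <- rejected
  out
}
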