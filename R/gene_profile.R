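# Strand-resolved metagene profiles across expression quartiles with
# dipyrimidine-content normalization.

#' Stratify genes into expression quartiles
#'
#' Quartile boundaries are the 25/50/75 percentiles of the expression
#' values; genes exactly on a boundary go to the lower quartile, ties keep
#' input order.
#'
#' @param genes tibble with an `expression` column (>= 4 finite values).
#' @return `genes` with an integer `quartile` column (1 = lowest).
#' @export
expression_quartiles <- function(genes) {
  e <- genes$expression
  if (sum(is.finite(e)) < 4L) abort("expression_quartiles: need >= 4 finite values")
  if (length(unique(e[is.finite(e)])) == 1L) {
    abort("expression_quartiles: all expression values equal")
  }
  qs <- quantile(e, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  genes$quartile <- 1L + (e > qs[1]) + (e > qs[2]) + (e > qs[3])
  genes
}

# Bin boundaries (0-based, genomic left-to-right) for one gene, or NULL if
# the gene is too short to bin.
gene_bins <- function(start, end, chrom_len, flank, flank_bins, body_bins) {
  L <- end - start
  if (L < body_bins) return(NULL)
  body <- start + floor(seq(0, body_bins) * L / body_bins)
  up <- start - flank * seq(flank_bins, 0)
  down <- end + flank * seq(0, flank_bins)
  edges <- c(up[-length(up)], body, down[-1])
  clipped <- pmin(pmax(edges, 0L), chrom_len)
  list(edges = clipped, clipped = any(edges != clipped))
}

# Assign 0-based positions to bins (1..n_bins in genomic order); NA outside.
assign_bin <- function(pos, edges) {
  findInterval(pos, edges, rightmost.closed = FALSE, left.open = FALSE) |>
    (\(i) ifelse(pos >= edges[1] & pos < edges[length(edges)], i, NA_integer_))()
}

#' Binned strand-resolved metagene profile
#'
#' Splits each gene into `body_bins` bins of equal fractional length
#' (lengths differ by at most one base) plus `flank_bins_per_side` fixed
#' `flank`-bp bins upstream and downstream, assigns lesions (by the genomic
#' position of their 5' base on the lesion strand) or mutations (by
#' position, strand taken as the strand whose ref base is the pyrimidine) to
#' bins and to a transcribed / non-transcribed strand class, and normalizes
#' counts by the per-bin per-strand number of (overlapping) dipyrimidine
#' occurrences. Bins are reported 5'->3' in gene orientation; the
#' transcribed (template) strand of a plus-strand gene is the minus strand.
#' If `genes` carries a `quartile` column the profile is computed per
#' quartile.
#'
#' @param genes gene tibble (`chrom`, `start`, `end`, `strand`, optional
#'   `quartile`); genes shorter than `body_bins` bases are skipped (logged).
#' @param records lesion tibble (two-base intervals with `strand`) or
#'   mutation tibble (`pos`, `ref`).
#' @param genome `DNAStringSet`.
#' @param flank flank bin width in bp (default 5000).
#' @param flank_bins_per_side number of flank bins on each side (default 2).
#' @param body_bins number of gene-body bins (default 6).
#' @param verbose log counts.
#' @return tibble: `quartile` (if present), `bin` (1..n, 5'->3'),
#'   `bin_label`, `strand_class`, `count`, `dipyrimidines`, `normalized`.
#' @export
binned_strand_profile <- function(genes, records, genome, flank = 5000L,
                                  flank_bins_per_side = 2L, body_bins = 6L,
                                  verbose = FALSE) {
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("binned_strand_profile: genes must be stranded")
  }
  is_mutation <- "pos" %in% names(records) && !"dinuc" %in% names(records)
  if (is_mutation) {
    rec <- tibble(chrom = records$chrom, pos = records$pos - 1L,
                  strand = ifelse(records$ref %in% PYRIMIDINES, "+", "-"))
  } else {
    rec <- tibble(chrom = records$chrom,
                  pos = ifelse(records$strand == "+", records$start,
                               records$end - 1L),
                  strand = records$strand)
  }
  n_bins <- body_bins + 2L * flank_bins_per_side
  lens <- genome_lengths(genome)
  acc <- list(); skipped <- 0L; clipped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cl <- lens$length[match(g$chrom, lens$chrom)]
    b <- gene_bins(g$start, g$end, cl, flank, flank_bins_per_side, body_bins)
    if (is.null(b)) { skipped <- skipped + 1L; next }
    clipped <- clipped + b$clipped
    edges <- b$edges
    # records on this chromosome within territory
    r <- rec[rec$chrom == g$chrom & rec$pos >= edges[1] &
               rec$pos < edges[length(edges)], ]
    gbin <- assign_bin(r$pos, edges)
    # genomic bin -> gene-oriented bin
    obin <- if (g$strand == "+") gbin else (n_bins + 1L - gbin)
    sclass <- ifelse(r$strand == g$strand, "non_transcribed", "transcribed")
    # dipyrimidine occurrences per bin/strand, 5' base assignment
    s <- genome_seq(genome, g$chrom, edges[1], edges[length(edges)])
    pos1 <- seq_len(nchar(s) - 1L)
    b1 <- substring(s, pos1, pos1)
    b2 <- substring(s, pos1 + 1L, pos1 + 1L)
    plus_dipy <- b1 %in% PYRIMIDINES & b2 %in% PYRIMIDINES
    minus_dipy <- b1 %in% PURINES & b2 %in% PURINES
    dp <- tibble(
      pos = c(edges[1] + pos1[plus_dipy] - 1L,          # + strand: 5' = left
              edges[1] + pos1[minus_dipy]),             # - strand: 5' = right
      strand = rep(c("+", "-"), c(sum(plus_dipy), sum(minus_dipy)))
    )
    dbin <- assign_bin(dp$pos, edges)
    dobin <- if (g$strand == "+") dbin else (n_bins + 1L - dbin)
    dclass <- ifelse(dp$strand == g$strand, "non_transcribed", "transcribed")
    q <- if ("quartile" %in% names(genes)) g$quartile else NA_integer_
    acc[[length(acc) + 1L]] <- dplyr::bind_rows(
      tibble(quartile = q, bin = obin, strand_class = sclass,
             what = "count", w = 1)[!is.na(obin), ],
      tibble(quartile = q, bin = dobin, strand_class = dclass,
             what = "dipy", w = 1)[!is.na(dobin), ]
    )
  }
  if (skipped > 0L && verbose) {
    inform(sprintf("[binned_strand_profile] skipped %d short gene(s)", skipped))
  }
  if (clipped > 0L && verbose) {
    inform(sprintf("[binned_strand_profile] clipped flanks on %d gene(s)", clipped))
  }
  long <- dplyr::bind_rows(acc)
  labels <- c(paste0("upstream_", seq_len(flank_bins_per_side)),
              paste0("body_", seq_len(body_bins)),
              paste0("downstream_", seq_len(flank_bins_per_side)))
  grid <- tidyr::expand_grid(
    quartile = unique(if ("quartile" %in% names(genes)) genes$quartile else NA_integer_),
    bin = seq_len(n_bins),
    strand_class = c("transcribed", "non_transcribed")
  )
  out <- long |>
    dplyr::group_by(.data$quartile, .data$bin, .data$strand_class, .data$what) |>
    dplyr::summarise(n = sum(.data$w), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "what", values_from = "n", values_fill = 0)
  for (col in c("count", "dipy")) if (!col %in% names(out)) out[[col]] <- 0
  out <- grid |>
    dplyr::left_join(out, by = c("quartile", "bin", "strand_class")) |>
    dplyr::mutate(
      count = ifelse(is.na(.data$count), 0, .data$count),
      dipy = ifelse(is.na(.data$dipy), 0, .data$dipy),
      bin_label = labels[.data$bin],
      normalized = ifelse(.data$dipy > 0, .data$count / .data$dipy, NA_real_)
    ) |>
    dplyr::select("quartile", "bin", "bin_label", "strand_class", "count",
                  dipyrimidines = "dipy", "normalized")
  attr(out, "skipped") <- skipped
  out
}
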