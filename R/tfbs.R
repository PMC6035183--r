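# TFBS curation, midpoints and ETS-motif alignment.

#' Curate a TFBS set
#'
#' Applies the standard binding-site curation cascade: discard sites whose
#' motif is `discovered` rather than `known`; merge overlapping sites of the
#' same TF into a single interval (union); flag sites overlapping a promoter
#' window as `promoter_proximal`; flag promoter-proximal sites overlapping a
#' DNase I hypersensitive site (>= 1 bp) as `active`; remove any site
#' overlapping a blacklist interval. Merged sites keep the strand when all
#' members agree, otherwise ".".
#'
#' @param tfbs tibble from [read_intervals()] with `name` (TF) and
#'   `motif_class` columns.
#' @param promoters,dhs,blacklist interval tibbles (may have zero rows).
#' @param verbose log per-step counts.
#' @return tibble of curated sites with columns `chrom`, `start`, `end`,
#'   `tf`, `strand`, `promoter_proximal`, `active`; attribute `"steps"`
#'   records per-step input/kept counts.
#' @export
curate_tfbs <- function(tfbs, promoters, dhs, blacklist, verbose = FALSE) {
  if (nrow(tfbs) == 0L) abort("curate_tfbs: empty TFBS input")
  steps <- list()
  n0 <- nrow(tfbs)
  known <- tfbs[tfbs$motif_class == "known", ]
  steps$known_motif <- log_filter("curate:known_motif", n0, nrow(known), verbose)

  # merge overlapping same-TF sites (union of intervals)
  merged <- known |>
    dplyr::group_by(.data$name) |>
    dplyr::group_modify(function(df, key) {
      gr <- GenomicRanges::reduce(as_granges0(df))
      hit <- overlap_hits(
        tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr)),
        df)
      str_per <- vapply(split(df$strand[hit$subject], hit$query), function(s) {
        s <- unique(s); if (length(s) == 1L) s else "."
      }, character(1))
      tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = unname(str_per[as.character(seq_along(gr))]))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(tf = "name") |>
    dplyr::select("chrom", "start", "end", "tf", "strand") |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$tf)
  steps$merge <- log_filter("curate:merge", nrow(known), nrow(merged), verbose)

  merged$promoter_proximal <- has_overlap(merged, promoters)
  merged$active <- merged$promoter_proximal & has_overlap(merged, dhs)

  keep <- !has_overlap(merged, blacklist)
  out <- merged[keep, ]
  steps$blacklist <- log_filter("curate:blacklist", nrow(merged), nrow(out), verbose)
  attr(out, "steps") <- steps
  out
}

#' Midpoint of binding-site intervals
#'
#' The midpoint is the mean of the first and last base (inclusive
#' coordinates, i.e. `start` and `end - 1`). In `simple` mode a fractional
#' mean is rounded up; in `strand_aware` mode it is rounded up on the plus
#' strand and down on the minus strand (sites with strand "." round up).
#'
#' @param sites interval tibble (needs `strand` for `strand_aware`).
#' @param mode `"simple"` or `"strand_aware"`.
#' @return `sites` with an integer `midpoint` column added.
#' @examples
#' site_midpoint(tibble::tibble(chrom = "c", start = 100L, end = 110L,
#'                              strand = c("+", "-")), "strand_aware")
#' @export
site_midpoint <- function(sites, mode = c("simple", "strand_aware")) {
  mode <- match.arg(mode)
  m <- (sites$start + sites$end - 1) / 2
  if (mode == "simple") {
    mp <- ceiling(m)
  } else {
    mp <- ifelse(sites$strand == "-", floor(m), ceiling(m))
  }
  sites$midpoint <- as.integer(mp)
  sites
}

#' Keep the first site per (chrom, midpoint)
#'
#' When several binding sites share a midpoint only the first instance (in
#' input order) is retained, so each aligned position is counted once.
#'
#' @param sites tibble with `chrom` and `midpoint` columns.
#' @param verbose log counts.
#' @return deduplicated tibble.
#' @export
dedupe_midpoints <- function(sites, verbose = FALSE) {
  n0 <- nrow(sites)
  out <- dplyr::distinct(sites, .data$chrom, .data$midpoint, .keep_all = TRUE)
  log_filter("dedupe_midpoints", n0, nrow(out), verbose)
  out
}

#' Align ETS-family sites at the TTCC core consensus
#'
#' ETS binding sites are aligned so that offset 0 is the first C of the
#' central CC in the TTCC core (the lesion-forming TC step then spans
#' offsets -1/0 and the CC step 0/+1). Each site's motif consensus is looked
#' up in a catalog (`tf`, `consensus`, `anchor_offset`: 0-based index of the
#' anchor C within the consensus); the consensus is searched on both genomic
#' strands of the site and the orientation is the strand carrying it.
#' Aligned midpoints are deduplicated per (chrom, midpoint), keeping the
#' first instance.
#'
#' @param sites curated site tibble with a `tf` column.
#' @param genome `DNAStringSet`.
#' @param catalog tibble with `tf`, `consensus`, `anchor_offset`.
#' @return tibble (`chrom`, `midpoint`, `orientation`, `tf`) of aligned
#'   anchors; sites whose sequence lacks the consensus raise an error.
#' @export
ets_align <- function(sites, genome, catalog) {
  miss <- setdiff(unique(sites$tf), catalog$tf)
  if (length(miss)) abort(paste0("ets_align: motif(s) missing from catalog: ",
                                 paste(miss, collapse = ", ")))
  idx <- match(sites$tf, catalog$tf)
  cons <- toupper(catalog$consensus[idx])
  aoff <- as.integer(catalog$anchor_offset[idx])
  if (any(!grepl("TTCC", cons, fixed = TRUE))) {
    abort("ets_align: every catalog consensus must contain the TTCC core")
  }
  seqs <- genome_seq(genome, sites$chrom, sites$start, sites$end)
  fwd <- vapply(seq_along(seqs),
                function(i) regexpr(cons[i], seqs[i], fixed = TRUE)[1],
                numeric(1))
  rev_ <- vapply(seq_along(seqs),
                 function(i) regexpr(revcomp(cons[i]), seqs[i], fixed = TRUE)[1],
                 numeric(1))
  if (any(fwd < 0 & rev_ < 0)) {
    abort(sprintf("ets_align: site %d lacks its consensus on either strand",
                  which(fwd < 0 & rev_ < 0)[1]))
  }
  plus <- fwd > 0
  # plus: anchor at match start + anchor_offset; minus: the consensus runs
  # right-to-left, so the anchor sits at the mirrored index.
  mid <- ifelse(plus,
                sites$start + (fwd - 1L) + aoff,
                sites$start + (rev_ - 1L) + (nchar(cons) - 1L - aoff))
  out <- tibble(chrom = sites$chrom,
                midpoint = as.integer(mid),
                orientation = ifelse(plus, "+", "-"),
                tf = sites$tf)
  dplyr::distinct(out, .data$chrom, .data$midpoint, .keep_all = TRUE)
}

#' Default ETS motif catalog
#'
#' A single-entry catalog for the canonical CTTCCGG consensus with the
#' anchor (offset 0) at its fourth base, the first C of the central CC.
#'
#' @param tf TF names to include (all share the consensus).
#' @return catalog tibble.
#' @export
ets_catalog <- function(tf = "ETS1") {
  tibble(tf = tf, consensus = "CTTCCGG", anchor_offset = 3L)
}
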