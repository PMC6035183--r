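# Per-offset lesion/mutation profiles around site midpoints and the
# naked-DNA-scaled core/flank damage enrichment.

site_orientation <- function(sites) {
  ori <- col_or_null(sites, "orientation")
  if (!is.null(ori)) ifelse(ori == "-", -1L, 1L) else rep(1L, nrow(sites))
}

# (lesion, site) pairs with the oriented offsets of the lesion's two bases.
lesion_site_offsets <- function(lesions, sites, halfwidth) {
  win <- tibble(chrom = sites$chrom,
                start = sites$midpoint - halfwidth,
                end = sites$midpoint + halfwidth + 1L)
  hits <- overlap_hits(lesions, win)
  sgn <- site_orientation(sites)[hits$subject]
  m <- sites$midpoint[hits$subject]
  b1 <- lesions$start[hits$query]
  o1 <- (b1 - m) * sgn
  o2 <- (b1 + 1L - m) * sgn
  tibble(lesion = hits$query, site = hits$subject,
         off1 = pmin(o1, o2), off2 = pmax(o1, o2))
}

new_position_profile <- function(df, n_sites, lesion_class, resolution) {
  structure(df, n_sites = n_sites, lesion_class = lesion_class,
            resolution = resolution,
            class = c("position_profile", class(df)))
}

#' Per-offset lesion profile around site midpoints
#'
#' Counts lesions at each position relative to aligned site midpoints and
#' divides by the number of unique sites. In `integer` resolution each
#' two-base lesion contributes one count at each of its base offsets inside
#' `[-halfwidth, +halfwidth]`; in `fractional` resolution it contributes one
#' count at the half-integer midpoint of its two bases (included iff within
#' `[-halfwidth + 0.5, +halfwidth - 0.5]`). Lesions on both strands are
#' combined; for oriented site sets (an `orientation` column, e.g. from
#' [ets_align()]) offsets are expressed in motif orientation.
#'
#' @param lesions lesion tibble from [call_cpd()] (or any two-base records).
#' @param sites tibble with `chrom`, `midpoint` and optional `orientation`;
#'   should already be deduplicated with [dedupe_midpoints()].
#' @param halfwidth window half-width in bp (default 100).
#' @param resolution `"integer"` or `"fractional"`.
#' @param combine_strands combine lesion strands (the default); if `FALSE`
#'   the profile carries a `strand` column with per-strand values.
#' @param lesion_class label stored on the result (`"CPD"`, `"mCPD"`, ...).
#' @return a `position_profile` tibble with `offset`, `count`, `value`
#'   (= count / n_sites) and attributes `n_sites`, `lesion_class`,
#'   `resolution`.
#' @export
position_profile <- function(lesions, sites, halfwidth = 100L,
                             resolution = c("integer", "fractional"),
                             combine_strands = TRUE, lesion_class = "CPD") {
  resolution <- match.arg(resolution)
  if (halfwidth <= 0) abort("position_profile: halfwidth must be positive")
  if (nrow(sites) == 0L) abort("position_profile: empty site set")
  n_sites <- nrow(sites)
  po <- lesion_site_offsets(lesions, sites, halfwidth)
  lstrand <- col_or_null(lesions, "strand") %||% rep(".", nrow(lesions))
  W <- halfwidth
  if (resolution == "integer") {
    long <- tibble(offset = c(po$off1, po$off2),
                   strand = rep(lstrand[po$lesion], 2L))
    long <- long[long$offset >= -W & long$offset <= W, ]
    grid <- seq(-W, W)
  } else {
    long <- tibble(offset = (po$off1 + po$off2) / 2,
                   strand = lstrand[po$lesion])
    long <- long[long$offset >= -(W - 0.5) & long$offset <= (W - 0.5), ]
    grid <- seq(-W + 0.5, W - 0.5)
  }
  if (combine_strands) {
    cnt <- dplyr::count(long, .data$offset, name = "count")
    df <- tibble(offset = grid) |>
      dplyr::left_join(cnt, by = "offset") |>
      dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
                    value = .data$count / n_sites)
  } else {
    cnt <- dplyr::count(long, .data$strand, .data$offset, name = "count")
    df <- tidyr::expand_grid(strand = unique(lstrand), offset = grid) |>
      dplyr::left_join(cnt, by = c("strand", "offset")) |>
      dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
                    value = .data$count / n_sites)
  }
  new_position_profile(df, n_sites, lesion_class, resolution)
}

#' Per-offset observed mutation profile
#'
#' Counts mutations at each oriented offset from site midpoints and divides
#' by the number of sites.
#'
#' @param mutations mutation tibble (`chrom`, 1-based `pos`).
#' @param sites deduplicated midpoint tibble (optional `orientation`).
#' @param halfwidth window half-width in bp.
#' @return a `position_profile` with `lesion_class = "mutation"`.
#' @export
mutation_profile <- function(mutations, sites, halfwidth = 100L) {
  if (nrow(sites) == 0L) abort("mutation_profile: empty site set")
  pos0 <- tibble(chrom = mutations$chrom, start = mutations$pos - 1L,
                 end = mutations$pos)
  win <- tibble(chrom = sites$chrom,
                start = sites$midpoint - halfwidth,
                end = sites$midpoint + halfwidth + 1L)
  hits <- overlap_hits(pos0, win)
  off <- (pos0$start[hits$query] - sites$midpoint[hits$subject]) *
    site_orientation(sites)[hits$subject]
  cnt <- dplyr::count(tibble(offset = off), .data$offset, name = "count")
  df <- tibble(offset = seq(-halfwidth, halfwidth)) |>
    dplyr::left_join(cnt, by = "offset") |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
                  value = .data$count / nrow(sites))
  new_position_profile(df, nrow(sites), "mutation", "integer")
}

#' Promoter scale factor between cells and naked-DNA lesion sets
#'
#' The naked-DNA control is sequenced at a different depth than the cellular
#' sample, so raw cells/naked ratios are normalized so that the overall
#' cells/naked ratio in promoter-proximal territory equals 1. The factor is
#' the ratio of lesion counts overlapping the promoter intervals.
#'
#' @param cells,naked lesion tibbles.
#' @param promoters promoter interval tibble.
#' @return scale factor `f` (a single number > 0).
#' @export
promoter_scale_factor <- function(cells, naked, promoters) {
  nc <- sum(has_overlap(cells, promoters))
  nn <- sum(has_overlap(naked, promoters))
  if (nn == 0L) abort("promoter_scale_factor: no naked-DNA lesions in promoters")
  if (nc == 0L) abort("promoter_scale_factor: no cellular lesions in promoters")
  nc / nn
}

#' Core/flank damage enrichment per TF
#'
#' For each TF, counts lesion bases at core offsets (default -4..+4 around
#' the midpoint) and flank offsets (default 5..100 bp away on either side)
#' in the cellular and naked-DNA datasets, and reports the promoter-scaled
#' enrichment `(core_cells / core_naked) / f`. The scalar
#' `total_core_lesions` counts whole lesions in the cellular dataset: a
#' lesion with both bases in the core counts 1 and a lesion straddling the
#' core boundary (offsets -5/-4 or +4/+5) counts 0.5; per-base counts in the
#' ratio are unaffected. TFs with fewer than `min_lesions` core lesion
#' counts in either dataset are flagged `included = FALSE`.
#'
#' @param sites deduplicated midpoint tibble with a `tf` column (optional
#'   `orientation`).
#' @param cells,naked lesion tibbles.
#' @param f promoter scale factor from [promoter_scale_factor()].
#' @param core integer length-2 core offset range (default `c(-4, 4)`).
#' @param flank length-2 absolute offset range for the flank (default
#'   `c(5, 100)`).
#' @param min_lesions inclusion threshold on core counts (default 5).
#' @return a `cpd_enrichment` tibble, one row per TF.
#' @export
core_flank_enrichment <- function(sites, cells, naked, f,
                                  core = c(-4L, 4L), flank = c(5L, 100L),
                                  min_lesions = 5L) {
  if (!"tf" %in% names(sites)) abort("core_flank_enrichment: sites need a 'tf' column")
  if (!is.numeric(f) || length(f) != 1L || f <= 0) {
    abort("core_flank_enrichment: f must be a single positive number")
  }
  W <- max(abs(core), flank[2])
  per_tf <- function(lesions) {
    po <- lesion_site_offsets(lesions, sites, W)
    tf <- sites$tf[po$site]
    off <- c(po$off1, po$off2)
    tf2 <- c(tf, tf)
    in_core <- off >= core[1] & off <= core[2]
    in_flank <- abs(off) >= flank[1] & abs(off) <= flank[2]
    # whole-lesion core totals with the 0.5 boundary rule
    n_in <- (po$off1 >= core[1] & po$off1 <= core[2]) +
      (po$off2 >= core[1] & po$off2 <= core[2])
    lesion_w <- ifelse(n_in == 2L, 1, ifelse(n_in == 1L, 0.5, 0))
    list(
      core = tapply(in_core, tf2, sum),
      flank = tapply(in_flank, tf2, sum),
      total = tapply(lesion_w, tf, sum)
    )
  }
  cc <- per_tf(cells)
  nk <- per_tf(naked)
  tfs <- sort(unique(sites$tf))
  g <- function(v, tf) ifelse(is.na(v[tf]), 0, v[tf])
  out <- tibble(
    tf = tfs,
    core_cells = as.numeric(g(cc$core, tfs)),
    core_naked = as.numeric(g(nk$core, tfs)),
    flank_cells = as.numeric(g(cc$flank, tfs)),
    flank_naked = as.numeric(g(nk$flank, tfs)),
    total_core_lesions = as.numeric(g(cc$total, tfs)),
    scale_factor = f
  ) |>
    dplyr::mutate(
      core_enrichment = ifelse(.data$core_naked > 0,
                               (.data$core_cells / .data$core_naked) / f, NA_real_),
      flank_enrichment = ifelse(.data$flank_naked > 0,
                                (.data$flank_cells / .data$flank_naked) / f, NA_real_),
      undefined = .data$core_naked == 0 & .data$core_cells > 0,
      included = .data$core_cells >= min_lesions &
        .data$core_naked >= min_lesions & !.data$undefined
    )
  structure(out, class = c("cpd_enrichment", class(out)))
}

#' Scaled enrichment between two profiles over an offset range
#'
#' Ratio of summed counts between a cells and a naked-DNA
#' [position_profile()] over an offset window, divided by the promoter
#' scale factor. At fractional resolution the window captures whole
#' dipyrimidine steps, which makes this the estimator of choice for
#' recovering a fold elevation planted at specific steps.
#'
#' @param cells,naked `position_profile` objects on the same grid.
#' @param f promoter scale factor.
#' @param range length-2 offset range (inclusive).
#' @return a single enrichment value.
#' @export
profile_enrichment <- function(cells, naked, f, range = c(-4, 4)) {
  sel_c <- cells$offset >= range[1] & cells$offset <= range[2]
  sel_n <- naked$offset >= range[1] & naked$offset <= range[2]
  nk <- sum(naked$count[sel_n])
  if (nk == 0) abort("profile_enrichment: no naked-DNA counts in range")
  (sum(cells$count[sel_c]) / nk) / f
}

#' @export
glance.cpd_enrichment <- function(x, ...) {
  tibble(n_tf = nrow(x),
         n_included = sum(x$included),
         median_core_enrichment = stats::median(x$core_enrichment[x$included]),
         median_flank_enrichment = stats::median(x$flank_enrichment[x$included]))
}
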