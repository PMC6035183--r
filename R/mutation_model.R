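# Trinucleotide-context expected-mutation model, observed/expected mutation
# enrichment, dipyrimidine mutation fraction and the mCPD-vs-mutation rank
# correlation.

#' All pyrimidine-centered trinucleotide contexts
#'
#' The 32 contexts N(C/T)N used by the signature model.
#' @return character vector of length 32.
#' @export
trinuc_contexts <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, paste0(c("C", "T"), rep(b, each = 2)),
                  function(x, y) paste0(x, y)))
}

# Fold a plus-strand trinucleotide to its pyrimidine-centered representation.
fold_context <- function(tri) {
  center <- substr(tri, 2, 2)
  ifelse(center %in% PYRIMIDINES, tri, revcomp(tri))
}

#' Fraction of mutations at dipyrimidine sequences
#'
#' A mutation is dipyrimidine-associated when the mutated base pair together
#' with either immediate neighbor forms a same-strand pyrimidine pair on
#' either DNA strand: on the plus strand both bases in {C,T}, or both in
#' {A,G} (a pyrimidine pair on the minus strand). Mutations at chromosome
#' edges are evaluated on the available neighbor(s).
#'
#' @param mutations mutation tibble with genome-consistent `ref`.
#' @param genome `DNAStringSet`.
#' @return fraction in `[0, 1]`.
#' @export
dipyrimidine_fraction <- function(mutations, genome) {
  if (nrow(mutations) == 0L) abort("dipyrimidine_fraction: no mutations")
  check_chrom(genome, mutations$chrom)
  len <- Biostrings::width(genome)[match(mutations$chrom, names(genome))]
  p0 <- mutations$pos - 1L
  pair_is_dipy <- function(a, b) {
    (a %in% PYRIMIDINES & b %in% PYRIMIDINES) |
      (a %in% PURINES & b %in% PURINES)
  }
  ctr <- genome_base(genome, mutations$chrom, p0)
  left <- rep(NA_character_, nrow(mutations))
  hasl <- p0 >= 1L
  left[hasl] <- genome_base(genome, mutations$chrom[hasl], p0[hasl] - 1L)
  right <- rep(NA_character_, nrow(mutations))
  hasr <- p0 + 1L < len
  right[hasr] <- genome_base(genome, mutations$chrom[hasr], p0[hasr] + 1L)
  hit <- (hasl & pair_is_dipy(left, ctr)) | (hasr & pair_is_dipy(ctr, right))
  mean(hit)
}

# Enumerate, for each territory interval, positions carrying a full
# trinucleotide inside the interval, with their folded contexts.
territory_contexts <- function(territory, genome) {
  territory <- territory[territory$end - territory$start >= 3L, ]
  purrr::pmap_dfr(
    list(territory$chrom, territory$start, territory$end),
    function(cm, s, e) {
      seq <- genome_seq(genome, cm, s, e)
      n <- nchar(seq)
      ctr <- 2:(n - 1)
      tri <- substring(seq, ctr - 1L, ctr + 1L)
      ok <- !grepl("N", tri, fixed = TRUE)
      tibble(chrom = cm, pos0 = s + ctr[ok] - 1L, context = fold_context(tri[ok]))
    }
  )
}

#' Fit a trinucleotide mutation signature
#'
#' Computes, for each of the 32 pyrimidine-centered trinucleotide contexts,
#' the mutation rate = mutations at that context / occurrences of the
#' context within the territory. Purine-centered mutations are folded to the
#' pyrimidine strand (context reverse-complemented); positions at territory
#' edges without a full trinucleotide inside the interval are excluded from
#' both numerator and denominator. Overlapping territory intervals are
#' reduced to a disjoint set first.
#'
#' @param mutations mutation tibble (positions 1-based).
#' @param territory interval tibble defining the estimation territory.
#' @param genome `DNAStringSet`.
#' @param verbose log counts.
#' @return a `trinuc_signature` tibble: `context`, `n_mutations`,
#'   `n_context`, `rate` (NA where the context never occurs).
#' @export
fit_signature <- function(mutations, territory, genome, verbose = FALSE) {
  if (nrow(territory) == 0L) abort("fit_signature: empty territory")
  terr <- tibble(chrom = territory$chrom, start = territory$start,
                 end = territory$end)
  gr <- GenomicRanges::reduce(as_granges0(terr))
  terr <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
  tc <- territory_contexts(terr, genome)
  if (nrow(tc) == 0L) abort("fit_signature: territory has no full trinucleotides")
  denom <- table(factor(tc$context, levels = trinuc_contexts()))
  key <- paste(tc$chrom, tc$pos0)
  mkey <- paste(mutations$chrom, mutations$pos - 1L)
  inside <- mkey %in% key
  log_filter("fit_signature:mutations_in_territory", nrow(mutations),
             sum(inside), verbose)
  mctx <- tc$context[match(mkey[inside], key)]
  num <- table(factor(mctx, levels = trinuc_contexts()))
  out <- tibble(
    context = trinuc_contexts(),
    n_mutations = as.integer(num),
    n_context = as.integer(denom),
    rate = ifelse(as.integer(denom) > 0,
                  as.integer(num) / as.integer(denom), NA_real_)
  )
  structure(out, class = c("trinuc_signature", class(out)),
            n_mutations_total = sum(out$n_mutations),
            n_positions = nrow(tc))
}

#' @export
tidy.trinuc_signature <- function(x, ...) {
  tibble(context = x$context, estimate = x$rate,
         n_mutations = x$n_mutations, n_context = x$n_context)
}

#' @export
glance.trinuc_signature <- function(x, ...) {
  tibble(n_mutations = attr(x, "n_mutations_total"),
         n_positions = attr(x, "n_positions"),
         n_defined_contexts = sum(!is.na(x$rate)),
         mean_rate = sum(x$n_mutations) / sum(x$n_context))
}

signature_rate <- function(signature, context) {
  r <- signature$rate[match(context, signature$context)]
  r
}

#' Expected mutation profile around site midpoints
#'
#' The expected mutation density at each offset is the mean, over unique
#' sites, of the fitted trinucleotide rate of the genomic position at that
#' offset. Each position contributes through its pyrimidine-folded context.
#' Positions whose context rate is undefined (context absent from the
#' estimation territory) or whose trinucleotide runs off the chromosome
#' contribute 0 and are counted in the `"undefined_context"` attribute.
#'
#' @param sites deduplicated midpoint tibble (optional `orientation`).
#' @param signature a `trinuc_signature` from [fit_signature()].
#' @param genome `DNAStringSet`.
#' @param halfwidth window half-width in bp.
#' @return a `position_profile` with `lesion_class = "expected_mutation"`;
#'   `count` holds the per-offset expected sums over sites.
#' @export
expected_profile <- function(sites, signature, genome, halfwidth = 100L) {
  if (nrow(sites) == 0L) abort("expected_profile: empty site set")
  W <- halfwidth
  sgn <- site_orientation(sites)
  len <- Biostrings::width(genome)[match(sites$chrom, names(genome))]
  grid <- seq(-W, W)
  # one window extraction per site (clipped at chromosome ends), then
  # vectorised substring contexts over the site x offset grid
  win_s <- pmax(sites$midpoint - W - 1L, 0L)
  win_e <- pmin(sites$midpoint + W + 2L, len)
  seqs <- genome_seq(genome, sites$chrom, win_s, win_e)
  pos <- rep(sites$midpoint, each = length(grid)) +
    rep(sgn, each = length(grid)) * grid
  site_i <- rep(seq_len(nrow(sites)), each = length(grid))
  ok <- pos >= 1L & pos + 1L < len[site_i] &
    pos - 1L >= win_s[site_i] & pos + 2L <= win_e[site_i]
  rel <- pos - win_s[site_i]  # 1-based index of the context start within seqs
  tri <- rep(NA_character_, length(pos))
  tri[ok] <- substring(seqs[site_i[ok]], rel[ok], rel[ok] + 2L)
  tri[!is.na(tri) & grepl("N", tri, fixed = TRUE)] <- NA
  r <- signature_rate(signature, fold_context(tri))
  undefined <- sum(is.na(r))
  total <- rowSums(matrix(ifelse(is.na(r), 0, r),
                          nrow = length(grid), ncol = nrow(sites)))
  df <- tibble(offset = grid, count = total, value = total / nrow(sites))
  out <- new_position_profile(df, nrow(sites), "expected_mutation", "integer")
  attr(out, "undefined_context") <- undefined
  out
}

#' Observed/expected mutation enrichment per TF
#'
#' Counts observed mutations at core offsets of each TF's deduplicated
#' sites, computes the expected count from the trinucleotide signature over
#' the same positions, and reports the observed/expected ratio. A TF is
#' included when it has at least `min_mutations` observed core mutations and
#' at least `min_sites` sites.
#'
#' @param sites deduplicated midpoint tibble with a `tf` column.
#' @param mutations mutation tibble.
#' @param signature a `trinuc_signature`.
#' @param genome `DNAStringSet`.
#' @param core core offset range (default `c(-4, 4)`).
#' @param min_mutations,min_sites inclusion thresholds (defaults 1 and 50).
#' @return a `mutation_enrichment` tibble, one row per TF: `tf`,
#'   `observed_core`, `expected_core`, `enrichment`, `n_sites`, `included`,
#'   `undefined`.
#' @export
mutation_enrichment <- function(sites, mutations, signature, genome,
                                core = c(-4L, 4L), min_mutations = 1L,
                                min_sites = 50L) {
  if (!"tf" %in% names(sites)) abort("mutation_enrichment: sites need a 'tf' column")
  half <- max(abs(core))
  res <- sites |>
    dplyr::group_by(.data$tf) |>
    dplyr::group_modify(function(df, key) {
      obs <- mutation_profile(mutations, df, halfwidth = half)
      exp_ <- expected_profile(df, signature, genome, halfwidth = half)
      sel <- obs$offset >= core[1] & obs$offset <= core[2]
      tibble(observed_core = sum(obs$count[sel]),
             expected_core = sum(exp_$count[sel]),
             n_sites = nrow(df))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      enrichment = ifelse(.data$expected_core > 0,
                          .data$observed_core / .data$expected_core, NA_real_),
      undefined = .data$expected_core == 0 & .data$observed_core > 0,
      included = .data$observed_core >= min_mutations &
        .data$n_sites >= min_sites & !.data$undefined
    )
  structure(res, class = c("mutation_enrichment", class(res)))
}

# All permutations of 1..n as a matrix (n! rows); n <= 9.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with exact small-n permutation p-value
#'
#' Computes Spearman's rho with average ranks for ties. The two-sided
#' p-value is computed by exhaustive permutation for `n <= 9` (probability
#' of |rho| at least as extreme under random pairing) and by the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise. Being
#' rank-based, the statistic is invariant under strictly increasing
#' transforms of either input.
#'
#' @param x,y paired numeric vectors (`n >= 4`).
#' @return one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
rank_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) abort("rank_correlation: need at least 4 paired values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("rank_correlation: rho undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- perm_matrix(n)
    rho_perm <- as.vector(cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  tibble(rho = rho, p_value = p, n = n, method = method)
}
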