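# Trinucleotide signature model, expected profiles, mutation enrichment,
# dipyrimidine fraction and the rank correlation.

uv_like_signature <- function(genome, territory) {
  # rates concentrated on contexts with a pyrimidine neighbor, UV-style
  sig <- fit_signature(empty_mutations(), territory, genome)
  nb_pyr <- substr(sig$context, 1, 1) %in% c("C", "T") |
    substr(sig$context, 3, 3) %in% c("C", "T")
  sig$rate <- ifelse(is.na(sig$rate), NA, ifelse(nb_pyr, 0.002, 0.0002))
  sig
}

test_that("dipyrimidine association checks both strands and neighbors", {
  g <- dna("ATCAGACAG", names = "chr1")
  # C at 1-based 3 in "TCA" -> TC pair on the plus strand
  expect_equal(dipyrimidine_fraction(
    tibble(chrom = "chr1", pos = 3L, ref = "C", alt = "T", donor = "d"), g), 1)
  # C at 1-based 7 in "ACA": neither strand has a pyrimidine pair
  expect_equal(dipyrimidine_fraction(
    tibble(chrom = "chr1", pos = 7L, ref = "C", alt = "T", donor = "d"), g), 0)
  # A in "CAG": minus-strand context CTG carries CT
  g2 <- dna("TTCAGTT", names = "chr1")
  expect_equal(dipyrimidine_fraction(
    tibble(chrom = "chr1", pos = 4L, ref = "A", alt = "T", donor = "d"), g2), 1)
  # chromosome edge: evaluated on the available neighbor only
  g3 <- dna("TTAAAA", names = "chr1")
  expect_equal(dipyrimidine_fraction(
    tibble(chrom = "chr1", pos = 1L, ref = "T", alt = "C", donor = "d"), g3), 1)
  # mutations from a TC/CT/CC-heavy generator are all dipyrimidine-associated
  pm <- plant_motifs(gen_genome(5e4, 0.5, seed = 61), n = 10,
                     min_spacing = 200, seed = 62)
  terr <- tibble(chrom = "chr1", start = 0L, end = 50000L)
  sig <- fit_signature(empty_mutations(), terr, pm$genome)
  dipy_ctx <- substr(sig$context, 1, 1) %in% c("C", "T") &
    substr(sig$context, 2, 2) == "C"
  sig$rate <- ifelse(is.na(sig$rate), NA, ifelse(dipy_ctx, 0.01, 0))
  gm <- gen_mutations(pm$genome, pm$sites[0, ], sig, n = 500, seed = 63)
  expect_equal(dipyrimidine_fraction(gm$mutations, pm$genome), 1)
})

test_that("signature rates are mutations over context occurrences, strand-folded", {
  g <- dna("ATCAT", names = "chr1")
  terr <- tibble(chrom = "chr1", start = 0L, end = 5L)
  m <- tibble(chrom = "chr1", pos = 3L, ref = "C", alt = "T", donor = "d")
  sig <- fit_signature(m, terr, g)
  expect_equal(sig$rate[sig$context == "TCA"], 1)
  # occurrences: positions 1..3 (0-based) have contexts TCA, CAT->ATG, ATC->GAT
  expect_equal(sum(sig$n_context), 3L)
  # purine-centered mutation folds to the pyrimidine strand
  g2 <- dna("ATGAT", names = "chr1")
  m2 <- tibble(chrom = "chr1", pos = 3L, ref = "G", alt = "T", donor = "d")
  sig2 <- fit_signature(m2, tibble(chrom = "chr1", start = 0L, end = 5L), g2)
  expect_equal(sig2$n_mutations[sig2$context == "TCA"], 1L)
  # no mutations: all defined rates are zero
  sig0 <- fit_signature(empty_mutations(), terr, g)
  expect_true(all(sig0$rate[!is.na(sig0$rate)] == 0))
  expect_error(fit_signature(m, tibble(chrom = "chr1", start = 0L, end = 2L), g),
               "no full trinucleotides")
})

test_that("expected profile is constant under a uniform signature", {
  g <- gen_genome(5000, 0.5, seed = 71)
  sig <- fit_signature(empty_mutations(),
                       tibble(chrom = "chr1", start = 0L, end = 5000L), g)
  sig$rate <- ifelse(is.na(sig$rate), NA, 0.003)
  ep <- expected_profile(tibble(chrom = "chr1", midpoint = 2500L), sig, g,
                         halfwidth = 50)
  expect_true(all(abs(ep$value - 0.003) < 1e-12))
  # single nonzero context: one nonzero offset
  sig1 <- sig
  sig1$rate <- ifelse(sig1$context == "TCA", 0.7, 0)
  left <- strrep("G", 60)
  g2 <- dna(paste0(left, "TCA", strrep("G", 60)), names = "chr1")
  ep1 <- expected_profile(tibble(chrom = "chr1", midpoint = 61L), sig1, g2, 20)
  expect_equal(ep1$value[ep1$offset == 0], 0.7)   # center C of TCA at 61
  expect_equal(sum(ep1$value > 0), 1L)
})

test_that("expected totals equal observed totals on the estimation territory", {
  pm <- plant_motifs(gen_genome(1e5, 0.4, seed = 81), n = 100,
                     min_spacing = 150, seed = 82)
  terr <- tibble(chrom = "chr1", start = 0L, end = 100000L)
  gm <- gen_mutations(pm$genome, pm$sites, uv_like_signature(pm$genome, terr),
                      hotspots = tibble(offset = 0L, fold = 10),
                      n = 4000, seed = 83)
  sig <- fit_signature(gm$mutations, terr, pm$genome)
  tc <- cpdseqr:::territory_contexts(terr, pm$genome)
  expected_total <- sum(sig$rate[match(tc$context, sig$context)], na.rm = TRUE)
  expect_equal(expected_total, nrow(gm$mutations), tolerance = 1e-9)
})

test_that("mutation enrichment applies observed/expected and inclusion rules", {
  pm <- plant_motifs(gen_genome(1e5, 0.4, seed = 91), n = 100,
                     min_spacing = 150, seed = 92)
  terr <- tibble(chrom = "chr1", start = 0L, end = 100000L)
  sites <- ets_align(pm$sites, pm$genome, pm$catalog) |>
    dplyr::mutate(tf = "ETS1")
  gm <- gen_mutations(pm$genome, pm$sites[0, ],
                      uv_like_signature(pm$genome, terr), n = 3000, seed = 93)
  sig <- fit_signature(gm$mutations, terr, pm$genome)
  me <- mutation_enrichment(sites, gm$mutations, sig, pm$genome)
  expect_equal(me$enrichment, me$observed_core / me$expected_core)
  expect_true(me$included)  # 100 sites >= 50 and observed >= 1
  # fewer than 50 sites -> excluded
  me40 <- mutation_enrichment(sites[1:40, ], gm$mutations, sig, pm$genome)
  expect_false(me40$included)
  expect_equal(me40$n_sites, 40)
})

test_that("planted 10x hotspot at offset 0 peaks there and nowhere else", {
  pm <- plant_motifs(gen_genome(2e5, 0.4, seed = 101), n = 400,
                     min_spacing = 150, seed = 102)
  terr <- tibble(chrom = "chr1", start = 0L, end = 200000L)
  sites <- ets_align(pm$sites, pm$genome, pm$catalog)
  gm <- gen_mutations(pm$genome, pm$sites,
                      uv_like_signature(pm$genome, terr),
                      hotspots = tibble(offset = 0L, fold = 10),
                      n = 15000, seed = 103)
  sig <- fit_signature(gm$mutations, terr, pm$genome)
  obs <- mutation_profile(gm$mutations, sites, 100)
  expd <- expected_profile(sites, sig, pm$genome, 100)
  ratio <- obs$value / pmax(expd$value, 1e-12)
  expect_equal(obs$offset[which.max(ratio)], 0)
  off_peak <- abs(obs$offset) > 5
  expect_gt(ratio[obs$offset == 0], 3 * stats::median(ratio[off_peak]))
})

test_that("null mutation enrichment centers on 1 across replicates", {
  pm <- plant_motifs(gen_genome(1e5, 0.4, seed = 111), n = 200,
                     min_spacing = 150, seed = 112)
  terr <- tibble(chrom = "chr1", start = 0L, end = 100000L)
  sites <- ets_align(pm$sites, pm$genome, pm$catalog) |>
    dplyr::mutate(tf = "ETS1")
  base <- uv_like_signature(pm$genome, terr)
  vals <- vapply(1:50, function(r) {
    g <- gen_mutations(pm$genome, pm$sites[0, ], base, n = 2500,
                       seed = 300 + r)
    s <- fit_signature(g$mutations, terr, pm$genome)
    mutation_enrichment(sites, g$mutations, s, pm$genome)$enrichment
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("rank correlation matches the exhaustive oracle and is rank-invariant", {
  # independent enumeration oracle, written from scratch here
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms_of(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  set.seed(5)
  x <- c(3.2, 1.1, 4.8, 2.7, 0.4)
  y <- c(10, 3, 8, 1, 7)
  res <- rank_correlation(x, y)
  rho_obs <- cor(rank(x), rank(y))
  rho_all <- vapply(perms_of(rank(y)),
                    function(p) cor(rank(x), p), numeric(1))
  p_oracle <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  expect_equal(res$rho, rho_obs)
  expect_equal(res$p_value, p_oracle)
  # cross-check against the standard implementation (distinct values, exact)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ct$estimate))
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  # monotone-transform invariance and sign
  expect_equal(rank_correlation(log(x), exp(y / 10))$rho, res$rho)
  expect_equal(rank_correlation(1:10, 2 * (1:10))$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)
  # t-approximation path for larger n
  set.seed(6)
  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  r2 <- rank_correlation(x2, y2)
  expect_equal(r2$method, "t approximation")
  expect_true(r2$p_value > 0 && r2$p_value < 1)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:3, 3:1), "at least 4")
})
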