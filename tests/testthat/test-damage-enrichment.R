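# Position profiles and naked-DNA-scaled core/flank enrichment.

test_that("profiles place lesion bases at integer and fractional offsets", {
  les <- tibble(chrom = "chr1", start = 99L, end = 101L, strand = "+",
                dinuc = "TT")
  st <- tibble(chrom = "chr1", midpoint = 100L)
  p <- position_profile(les, st, halfwidth = 5)
  expect_equal(p$value[p$offset %in% c(-1, 0)], c(1, 1))
  expect_equal(sum(p$count), 2L)
  pf <- position_profile(les, st, halfwidth = 5, resolution = "fractional")
  expect_equal(pf$value[pf$offset == -0.5], 1)
  expect_equal(sum(pf$count), 1L)
  # averaging over sites
  st2 <- tibble(chrom = "chr1", midpoint = c(100L, 500L))
  p2 <- position_profile(les, st2, halfwidth = 5)
  expect_equal(p2$value[p2$offset == -1], 0.5)
  expect_error(position_profile(les, st, halfwidth = 0), "positive")
})

test_that("profile orientation flips offsets for minus-oriented sites", {
  les <- tibble(chrom = "chr1", start = 103L, end = 105L, strand = "+",
                dinuc = "TT")
  st <- tibble(chrom = "chr1", midpoint = 100L, orientation = "-")
  p <- position_profile(les, st, halfwidth = 10)
  expect_equal(p$offset[p$count > 0], c(-4, -3))
  pf <- position_profile(les, st, halfwidth = 10, resolution = "fractional")
  expect_equal(pf$offset[pf$count > 0], -3.5)
})

test_that("count conservation holds on random inputs in both resolutions", {
  set.seed(11)
  pm <- plant_motifs(gen_genome(1e5, 0.4, seed = 12), n = 60,
                     min_spacing = 300, seed = 13)
  les <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, damage_model(), 5000,
                                "cells", seed = 14)$reads, pm$genome)
  sites <- ets_align(pm$sites, pm$genome, pm$catalog)
  W <- 100L
  p <- position_profile(les, sites, W)
  pf <- position_profile(les, sites, W, resolution = "fractional")
  # lesions fully inside some window (both bases in [-W, W])
  po <- cpdseqr:::lesion_site_offsets(les, sites, W)
  inside2 <- sum(po$off1 >= -W & po$off2 <= W)
  per_base <- sum(po$off1 >= -W & po$off1 <= W) + sum(po$off2 >= -W & po$off2 <= W)
  expect_equal(sum(p$count), per_base)
  expect_equal(sum(pf$count), inside2)
  expect_equal(sum(p$value) * nrow(sites), per_base)
  # a lesion straddling the window edge contributes its in-window base only
  st1 <- tibble(chrom = "chr1", midpoint = 1000L)
  edge <- tibble(chrom = "chr1", start = 1000L + W, end = 1002L + W,
                 strand = "+", dinuc = "TT")
  pe <- position_profile(edge, st1, W)
  expect_equal(sum(pe$count), 1L)
  pef <- position_profile(edge, st1, W, resolution = "fractional")
  expect_equal(sum(pef$count), 0L)
})

test_that("promoter scale factor normalizes promoter territory to exactly 1", {
  pm <- plant_motifs(gen_genome(2e5, 0.4, seed = 21), n = 100,
                     min_spacing = 150, seed = 22)
  cells <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, damage_model(), 20000,
                                  "cells", seed = 23)$reads, pm$genome)
  naked <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, damage_model(), 15000,
                                  "naked", seed = 24)$reads, pm$genome)
  prom <- tibble(chrom = "chr1", start = 0L, end = 200000L)
  f <- promoter_scale_factor(cells, naked, prom)
  expect_equal(f, nrow(cells) / nrow(naked))
  n_c <- sum(cpdseqr:::has_overlap(cells, prom))
  n_n <- sum(cpdseqr:::has_overlap(naked, prom))
  expect_equal((n_c / n_n) / f, 1, tolerance = 1e-12)
  expect_error(promoter_scale_factor(cells[0, ], naked, prom), "cellular")
  expect_error(promoter_scale_factor(cells, naked[0, ], prom), "naked")
})

test_that("core/flank enrichment applies scaling, thresholds and 0.5 boundary", {
  # constructed geometry: one TF, one site at midpoint 1000
  sites <- tibble(chrom = "chr1", midpoint = 1000L, tf = "TFX")
  mk <- function(offsets5) {
    tibble(chrom = "chr1", start = 1000L + as.integer(offsets5),
           end = 1002L + as.integer(offsets5), strand = "+", dinuc = "TT")
  }
  cells <- mk(rep(c(-1L, 0L), 20))        # 40 lesions fully in core
  naked <- mk(rep(-1L, 10))               # 10 lesions fully in core
  enr <- core_flank_enrichment(sites, cells, naked, f = 2)
  expect_equal(enr$core_cells, 80)        # per-base counts
  expect_equal(enr$core_naked, 20)
  expect_equal(enr$core_enrichment, (80 / 20) / 2)
  expect_true(enr$included)
  expect_equal(enr$total_core_lesions, 40)

  # boundary lesions at -5/-4 count 0.5 toward the lesion total, and only
  # their in-core base toward per-base counts
  cellsb <- mk(c(-5L, -5L, 4L))           # two at -5/-4, one at +4/+5
  enrb <- core_flank_enrichment(sites, cellsb, naked, f = 1)
  expect_equal(enrb$total_core_lesions, 1.5)
  expect_equal(enrb$core_cells, 3)        # one in-core base each

  # inclusion threshold: fewer than five core counts in either dataset
  enr4 <- core_flank_enrichment(sites, mk(c(-1L, 0L)), naked, f = 1)
  expect_false(enr4$included)             # 4 core cell counts < 5
  # undefined: naked empty in core but cells present
  enru <- core_flank_enrichment(sites, cells, mk(90L), f = 1)
  expect_true(enru$undefined)
  expect_true(is.na(enru$core_enrichment))
  expect_false(enru$included)
})

test_that("whole-territory enrichment after scaling is exactly 1", {
  pm <- plant_motifs(gen_genome(1e5, 0.45, seed = 31), n = 50,
                     min_spacing = 200, seed = 32)
  cells <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, damage_model(), 8000,
                                  "cells", seed = 33)$reads, pm$genome)
  naked <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, damage_model(), 6000,
                                  "naked", seed = 34)$reads, pm$genome)
  prom <- tibble(chrom = "chr1", start = 0L, end = 100000L)
  f <- promoter_scale_factor(cells, naked, prom)
  ratio <- (sum(cpdseqr:::has_overlap(cells, prom)) /
              sum(cpdseqr:::has_overlap(naked, prom))) / f
  expect_equal(ratio, 1, tolerance = 1e-12)
})

test_that("fold recovery: planted core elevation is recovered within 20%", {
  pm <- plant_motifs(gen_genome(4e5, 0.4, seed = 41), n = 1000,
                     min_spacing = 120, seed = 42)
  sites <- ets_align(pm$sites, pm$genome, pm$catalog) |>
    dplyr::mutate(tf = "ETS1")
  # promoter territory for depth scaling: everything further than 50 bp from
  # a planted site, so the scale factor measures sequencing depth alone (in
  # real promoters binding-site cores are a vanishing fraction of the
  # territory; at this toy scale they would otherwise dominate it)
  gaps <- GenomicRanges::gaps(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pm$sites$start - 49L, pm$sites$end + 50L)))
  prom <- tibble(chrom = "chr1",
                 start = GenomicRanges::start(gaps) - 1L,
                 end = GenomicRanges::end(gaps)) |>
    dplyr::filter(end <= 400000L, end > start)
  folds_core <- tibble(offset5 = -4:3, offset3 = -3:4, fold = 1)
  for (k in c(2, 5, 16)) {
    mod <- damage_model(folds = dplyr::mutate(folds_core, fold = k))
    cells <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, mod, 1e5, "cells",
                                    seed = 43)$reads, pm$genome)
    naked <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, mod, 1e5, "naked",
                                    seed = 44)$reads, pm$genome)
    f <- promoter_scale_factor(cells, naked, prom)
    est <- core_flank_enrichment(sites, cells, naked, f)$core_enrichment
    expect_gt(est, 0.8 * k)
    expect_lt(est, 1.2 * k)
  }
})

test_that("null damage enrichment centers on 1 across replicates", {
  pm <- plant_motifs(gen_genome(1e5, 0.4, seed = 51), n = 200,
                     min_spacing = 150, seed = 52)
  sites <- ets_align(pm$sites, pm$genome, pm$catalog) |>
    dplyr::mutate(tf = "ETS1")
  prom <- tibble(chrom = "chr1", start = 0L, end = 100000L)
  mod <- damage_model(folds = tibble(offset5 = integer(), offset3 = integer(),
                                     fold = numeric()))
  vals <- vapply(1:50, function(r) {
    cells <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, mod, 12000, "cells",
                                    seed = 100 + r)$reads, pm$genome)
    naked <- call_cpd(gen_cpd_reads(pm$genome, pm$sites, mod, 12000, "naked",
                                    seed = 200 + r)$reads, pm$genome)
    f <- promoter_scale_factor(cells, naked, prom)
    core_flank_enrichment(sites, cells, naked, f)$core_enrichment
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})
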