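# Synthetic-data generators with truth tables: toy genomes with planted ETS
# motifs, CPD-seq read ends with controllable position-specific damage
# elevation, signature-driven mutations with hotspots, XR-seq reads, and
# idealized B-DNA C5/C6 coordinates with closed-form (d, eta).
#
# Every generator is a deterministic function of (parameters, seed) and uses
# a local RNG stream, leaving the global RNG state untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random genome
#'
#' I.i.d. bases at a stated GC fraction; deterministic for a seed.
#'
#' @param length sequence length (> 0).
#' @param gc_fraction GC fraction in (0, 1) (0 and 1 allowed for degenerate
#'   A/T- or G/C-only genomes).
#' @param seed integer seed.
#' @param name chromosome name.
#' @return a single-chromosome `DNAStringSet`.
#' @export
gen_genome <- function(length, gc_fraction = 0.4, seed = 1L, name = "chr1") {
  if (length <= 0) abort("gen_genome: length must be positive")
  if (gc_fraction < 0 || gc_fraction > 1) abort("gen_genome: gc_fraction in [0,1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- with_seed(seed, sample(names(p), length, replace = TRUE, prob = p))
  g <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(g) <- name
  g
}

#' Plant ETS motifs into a genome
#'
#' Writes `n` copies of the motif (default the canonical CTTCCGG consensus)
#' at non-overlapping positions on random strands, with pairwise gaps of at
#' least `min_spacing`. A stated fraction of sites receives a pyrimidine (T)
#' at motif offset -4 (the base 5' of the consensus on the consensus
#' strand), mimicking the minority of ETS sites able to form a -4/-3 CPD;
#' the rest receive a purine (A) there.
#'
#' @param genome single-chromosome `DNAStringSet`.
#' @param motif consensus planted (must contain TTCC).
#' @param n number of sites.
#' @param min_spacing minimum gap between site intervals (bp).
#' @param seed integer seed.
#' @param variant_fraction_pyrimidine_minus4 fraction of sites with a
#'   pyrimidine at offset -4 (default 0.12).
#' @param tf TF name written to the site records.
#' @param anchor_offset 0-based index of the anchor C within `motif`
#'   (default 3 for CTTCCGG: the first C of the central CC).
#' @return list with `genome` (motifs written in), `sites` (tibble: BED6
#'   fields + `tf`, `motif_class`, `orientation`, `anchor` = genomic offset-0
#'   position, `pyr_minus4`), and `catalog` (for [ets_align()]).
#' @export
plant_motifs <- function(genome, motif = "CTTCCGG", n, min_spacing = 200L,
                         seed = 1L, variant_fraction_pyrimidine_minus4 = 0.12,
                         tf = "ETS1", anchor_offset = 3L) {
  if (length(genome) != 1L) abort("plant_motifs: single-chromosome genome expected")
  chrom <- names(genome)
  L <- Biostrings::width(genome)[1]
  w <- nchar(motif)
  slot <- w + min_spacing + 2L  # +2 margin so the -4 base stays inside
  n_slots <- (L - 2L * slot) %/% slot
  if (n_slots < n) abort("plant_motifs: cannot place n sites with this spacing")
  res <- with_seed(seed, {
    slots <- sort(sample(seq_len(n_slots), n))
    list(starts = slot + (slots - 1L) * slot,
         strands = sample(c("+", "-"), n, replace = TRUE),
         pyr = runif(n) < variant_fraction_pyrimidine_minus4)
  })
  s <- chrom_string(genome, chrom)
  seqs <- strsplit(s, "")[[1]]
  anchors <- integer(n)
  for (i in seq_len(n)) {
    st <- res$starts[i]
    if (res$strands[i] == "+") {
      seqs[(st + 1):(st + w)] <- strsplit(motif, "")[[1]]
      anchors[i] <- st + anchor_offset
      seqs[st] <- if (res$pyr[i]) "T" else "A"   # offset -4 at st - 1 (0-based)
    } else {
      seqs[(st + 1):(st + w)] <- strsplit(revcomp(motif), "")[[1]]
      # motif runs right-to-left: anchor mirrored within the interval
      anchors[i] <- st + (w - 1L - anchor_offset)
      # offset -4 on the consensus (minus) strand is the base right of the
      # interval; write the complement of T/A on the plus strand
      seqs[st + w + 4L - anchor_offset] <- if (res$pyr[i]) "A" else "T"
    }
  }
  g2 <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
  names(g2) <- chrom
  sites <- tibble(
    chrom = chrom, start = res$starts, end = res$starts + w,
    name = tf, score = 0, strand = res$strands,
    tf = tf, motif_class = "known", orientation = res$strands,
    anchor = anchors, pyr_minus4 = res$pyr
  )
  list(genome = g2, sites = sites,
       catalog = tibble(tf = tf, consensus = motif, anchor_offset = anchor_offset))
}

# Enumerate every dipyrimidine lesion site of a genome: plus-strand
# dipyrimidines lie on "+", plus-strand dipurines are dipyrimidines on "-".
enumerate_dipyrimidines <- function(genome, chrom = names(genome)[1]) {
  s <- chrom_string(genome, chrom)
  n <- nchar(s)
  pos1 <- seq_len(n - 1L)
  b1 <- substring(s, pos1, pos1)
  b2 <- substring(s, pos1 + 1L, pos1 + 1L)
  plus <- b1 %in% PYRIMIDINES & b2 %in% PYRIMIDINES
  minus <- b1 %in% PURINES & b2 %in% PURINES
  di_plus <- paste0(b1[plus], b2[plus])
  di_minus <- revcomp(paste0(b1[minus], b2[minus]))
  out <- tibble(
    chrom = chrom,
    start = c(pos1[plus] - 1L, pos1[minus] - 1L),
    strand = rep(c("+", "-"), c(sum(plus), sum(minus))),
    dinuc = c(di_plus, di_minus)
  )
  # keep lesions whose inverse read-end stays on the chromosome
  out[out$start >= 1L & out$start + 2L <= n - 1L, ]
}

#' Default damage model
#'
#' Baseline per-dinucleotide lesion weights follow the qualitative
#' photoreactivity ordering TT > TC = CT > CC; fold elevations default to
#' the ETS hotspot offsets -4/-3 (16x), -1/0 (8x) and 0/+1 (8x) relative to
#' the motif anchor, on the consensus strand.
#'
#' @param baseline named weights for TT, TC, CT, CC.
#' @param folds tibble with `offset5`, `offset3`, `fold`.
#' @return damage model list.
#' @export
damage_model <- function(baseline = c(TT = 1, TC = 0.6, CT = 0.6, CC = 0.3),
                         folds = tibble(offset5 = c(-4L, -1L, 0L),
                                        offset3 = c(-3L, 0L, 1L),
                                        fold = c(16, 8, 8))) {
  if (any(baseline <= 0) || any(folds$fold <= 0)) {
    abort("damage_model: weights and folds must be positive")
  }
  list(baseline = baseline, folds = folds)
}

#' Simulate CPD-seq read ends
#'
#' Samples lesions over all dipyrimidine sites with probability proportional
#' to the baseline dinucleotide weight, multiplied (for `dataset = "cells"`)
#' by the fold at the lesion's motif offset when it coincides with a
#' hotspot of a planted site; the naked-DNA dataset ignores the fold map.
#' For each sampled lesion the read-end record that [call_cpd()] inverts to
#' exactly that lesion is emitted: a lesion on the minus strand over
#' `[a, a+2)` yields a plus-strand read with 5' end `a+2`; a plus-strand
#' lesion yields a minus-strand read with 5' end `a-1`.
#'
#' @param genome `DNAStringSet` (typically from [plant_motifs()]).
#' @param sites planted site tibble with `anchor` and `orientation` (may be
#'   zero rows for a flat genome).
#' @param model damage model from [damage_model()].
#' @param n_reads number of reads to emit.
#' @param dataset `"cells"` (folds applied) or `"naked"`.
#' @param seed integer seed.
#' @param read_length nominal read length for the BED records.
#' @return list with `reads` (BED6-style tibble with `five_prime`), `truth`
#'   (sampled lesion tibble plus parameters).
#' @export
gen_cpd_reads <- function(genome, sites, model = damage_model(), n_reads,
                          dataset = c("cells", "naked"), seed = 1L,
                          read_length = 30L) {
  dataset <- match.arg(dataset)
  dipy <- enumerate_dipyrimidines(genome)
  if (nrow(dipy) == 0L) abort("gen_cpd_reads: genome contains no dipyrimidine")
  w <- unname(model$baseline[dipy$dinuc])
  if (dataset == "cells" && nrow(sites) > 0L && nrow(model$folds) > 0L) {
    # a fold at an offset pair elevates whichever strand's dipyrimidine
    # occupies those two bases (a 2-base position hosts at most one lesion)
    hot <- purrr::pmap_dfr(
      list(sites$anchor, sites$orientation),
      function(anchor, ori) {
        s <- if (ori == "-") -1L else 1L
        p <- cbind(anchor + s * model$folds$offset5,
                   anchor + s * model$folds$offset3)
        tibble(start = pmin(p[, 1], p[, 2]), fold = model$folds$fold)
      })
    m <- match(dipy$start, hot$start)
    w <- w * ifelse(is.na(m), 1, hot$fold[m])
  }
  idx <- with_seed(seed, sample.int(nrow(dipy), n_reads, replace = TRUE,
                                    prob = w / sum(w)))
  les <- dipy[idx, ]
  len <- Biostrings::width(genome)[match(les$chrom, names(genome))]
  fp <- ifelse(les$strand == "-", les$start + 2L, les$start - 1L)
  read_strand <- ifelse(les$strand == "-", "+", "-")
  start <- ifelse(read_strand == "+", fp, pmax(0L, fp - read_length + 1L))
  end <- ifelse(read_strand == "+", pmin(len, fp + read_length), fp + 1L)
  reads <- tibble(chrom = les$chrom, start = as.integer(start),
                  end = as.integer(end), name = "read", score = 0,
                  strand = read_strand, five_prime = as.integer(fp))
  truth <- list(lesions = tibble(chrom = les$chrom, start = les$start,
                                 end = les$start + 2L, strand = les$strand,
                                 dinuc = les$dinuc),
                model = model, dataset = dataset, n_reads = n_reads, seed = seed)
  list(reads = reads, truth = truth)
}

#' Simulate signature-driven mutations with motif hotspots
#'
#' Samples mutated positions with probability proportional to the
#' signature's rate for the position's pyrimidine-folded trinucleotide
#' context, multiplied by a hotspot fold at stated motif offsets of planted
#' sites. Alt bases are uniform over the three non-ref bases; donors are
#' assigned round-robin.
#'
#' @param genome `DNAStringSet`.
#' @param sites planted site tibble with `anchor`, `orientation` (may be
#'   zero rows).
#' @param signature a `trinuc_signature` (or tibble with `context`, `rate`).
#' @param hotspots tibble with `offset`, `fold` (motif offsets, consensus
#'   orientation); default none.
#' @param n number of mutations.
#' @param seed integer seed.
#' @param n_donors donor count for round-robin assignment (default 184).
#' @return list with `mutations` (tibble: chrom, 1-based pos, ref, alt,
#'   donor) and `truth` (per-position rates and parameters).
#' @export
gen_mutations <- function(genome, sites, signature,
                          hotspots = tibble(offset = integer(), fold = numeric()),
                          n, seed = 1L, n_donors = 184L) {
  chrom <- names(genome)[1]
  s <- chrom_string(genome, chrom)
  nb <- nchar(s)
  ctr <- 2:(nb - 1)
  tri <- substring(s, ctr - 1L, ctr + 1L)
  rate <- signature_rate(signature, fold_context(tri))
  rate[is.na(rate)] <- 0
  pos0 <- ctr - 1L  # 0-based position of the center base
  if (nrow(sites) > 0L && nrow(hotspots) > 0L) {
    sgn <- ifelse(sites$orientation == "-", -1L, 1L)
    hotpos <- as.vector(outer(hotspots$offset, seq_len(nrow(sites)),
                              function(o, i) sites$anchor[i] + sgn[i] * o))
    hotfold <- rep(hotspots$fold, nrow(sites))
    m <- match(pos0, hotpos)
    rate <- rate * ifelse(is.na(m), 1, hotfold[m])
  }
  if (all(rate == 0)) abort("gen_mutations: all-zero mutation rates")
  picks <- with_seed(seed, {
    i <- sample.int(length(pos0), n, replace = TRUE, prob = rate / sum(rate))
    alt_draw <- runif(n)
    list(i = i, alt_draw = alt_draw)
  })
  p <- pos0[picks$i]
  ref <- substring(s, p + 1L, p + 1L)
  others <- lapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b))
  alt <- vapply(seq_len(n),
                function(k) others[[k]][1L + floor(picks$alt_draw[k] * 3)],
                character(1))
  mutations <- tibble(
    chrom = chrom, pos = p + 1L, ref = ref, alt = alt,
    donor = sprintf("D%03d", ((seq_len(n) - 1L) %% n_donors) + 1L)
  )
  list(mutations = mutations,
       truth = list(hotspots = hotspots, n = n, seed = seed,
                    rate_by_pos = tibble(pos0 = pos0, rate = rate)))
}

#' Simulate XR-seq reads around known lesions
#'
#' Each read contains its source lesion's dipyrimidine with the 3' base at
#' an offset drawn from `offsets` upstream of the read's 3' end; the truth
#' table records the drawn offset. Reads that would extend past the
#' chromosome are dropped (counted).
#'
#' @param lesions lesion tibble (`chrom`, `start`, `end`, `strand`).
#' @param genome `DNAStringSet`.
#' @param read_lengths integer range of read lengths (default 20:30).
#' @param offsets candidate 3'-end offsets (default 6:8).
#' @param seed integer seed.
#' @return list with `reads` (BED6-style tibble) and `truth` (per-read
#'   offset and source lesion).
#' @export
gen_xrseq_reads <- function(lesions, genome, read_lengths = 20:30,
                            offsets = 6:8, seed = 1L) {
  n <- nrow(lesions)
  pick <- function(v, n) v[sample.int(length(v), n, replace = TRUE)]
  draw <- with_seed(seed, list(
    o = pick(as.integer(offsets), n),
    L = pick(as.integer(read_lengths), n)
  ))
  a <- lesions$start
  start <- ifelse(lesions$strand == "+",
                  a + 1L - (draw$L - 1L - draw$o),  # 3' base a+1 at index L-1-o
                  a - draw$o)                       # minus: end = a + L - o
  end <- start + draw$L
  len <- Biostrings::width(genome)[match(lesions$chrom, names(genome))]
  ok <- start >= 0L & end <= len
  reads <- tibble(chrom = lesions$chrom[ok], start = as.integer(start[ok]),
                  end = as.integer(end[ok]), name = "xr", score = 0,
                  strand = lesions$strand[ok])
  truth <- tibble(chrom = lesions$chrom[ok], lesion_start = a[ok],
                  strand = lesions$strand[ok], offset = draw$o[ok],
                  read_length = draw$L[ok])
  list(reads = reads, truth = truth, dropped_edge = sum(!ok))
}

#' Idealized B-DNA C5/C6 coordinates with closed-form step geometry
#'
#' Places C5/C6 atoms of each pyrimidine of a sequence on an ideal helix
#' (base i rotated by `i * twist` about z and translated by `i * rise`), and
#' records, for every consecutive-pyrimidine step, the analytic oracle:
#' `d = sqrt(4 sin^2(twist/2) |m_xy|^2 + rise^2)` with `m` the C5-C6 bond
#' midpoint of the reference base, and `eta` from the plane-normal dihedral
#' of the constructed four-atom chain (a formulation independent of
#' [step_geometry()]'s atan2 path). With `twist = 0`, `eta = 0` and
#' `d = rise` for every step.
#'
#' @param sequence DNA sequence (plus strand; purines get no atoms).
#' @param rise helical rise per base (Angstrom, default 3.38).
#' @param twist helical twist per base (degrees, default 36).
#' @return list with `atoms` (tibble usable by [scan_structure()]) and
#'   `steps` (tibble: `resno5`, `resno3`, `d`, `eta`).
#' @export
gen_bdna <- function(sequence, rise = 3.38, twist = 36) {
  if (rise <= 0) abort("gen_bdna: rise must be positive")
  bases <- strsplit(toupper(sequence), "")[[1]]
  # reference C5/C6 geometry (bond length ~1.35 A, off-axis)
  c5_0 <- c(4.5, 0.8, 0.0)
  c6_0 <- c(3.6, -0.2, 0.1)
  th <- twist * pi / 180
  rot <- function(v, k) {
    a <- k * th
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], v[3])
  }
  atoms <- list()
  for (i in seq_along(bases)) {
    if (!bases[i] %in% PYRIMIDINES) next
    p5 <- rot(c5_0, i - 1) + c(0, 0, (i - 1) * rise)
    p6 <- rot(c6_0, i - 1) + c(0, 0, (i - 1) * rise)
    resid <- if (bases[i] == "C") "DC" else "DT"
    atoms[[length(atoms) + 1L]] <- tibble(
      chain = "A", resno = i, resid = resid,
      elety = c("C5", "C6"),
      x = c(p5[1], p6[1]), y = c(p5[2], p6[2]), z = c(p5[3], p6[3]),
      occupancy = 1
    )
  }
  atoms <- dplyr::bind_rows(atoms)
  # closed-form oracle per consecutive-pyrimidine step
  m0 <- (c5_0 + c6_0) / 2
  d_closed <- sqrt(4 * sin(th / 2)^2 * sum(m0[1:2]^2) + rise^2)
  plane_normal_dihedral <- function(p1, p2, p3, p4) {
    n1 <- pracma_cross(p1 - p2, p3 - p2)
    n2 <- pracma_cross(p2 - p3, p4 - p3)
    acos(pmin(1, pmax(-1, sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  }
  steps <- list()
  pyr_idx <- which(bases %in% PYRIMIDINES)
  for (i in pyr_idx) {
    if (!((i + 1L) %in% pyr_idx)) next
    p5a <- rot(c5_0, i - 1) + c(0, 0, (i - 1) * rise)
    p6a <- rot(c6_0, i - 1) + c(0, 0, (i - 1) * rise)
    p5b <- rot(c5_0, i) + c(0, 0, i * rise)
    p6b <- rot(c6_0, i) + c(0, 0, i * rise)
    eta <- if (abs(th) < 1e-12) 0 else plane_normal_dihedral(p5a, p6a, p6b, p5b)
    steps[[length(steps) + 1L]] <- tibble(resno5 = i, resno3 = i + 1L,
                                          d = d_closed, eta = eta)
  }
  list(atoms = atoms,
       steps = if (length(steps)) dplyr::bind_rows(steps) else
         tibble(resno5 = integer(), resno3 = integer(), d = numeric(),
                eta = numeric()),
       params = list(rise = rise, twist = twist))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
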