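---
title: "UV damage and mutation enrichment at TF binding sites: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UV damage and mutation enrichment at TF binding sites: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdseqr)
library(dplyr)
library(tibble)
```

This vignette documents the models, conventions and numerical choices
behind `cpdseqr`, in the spirit of a methods section: what each statistic
assumes, which knobs matter, and what the synthetic-data tests do and do
not demonstrate about real data.

## Coordinate conventions

All genomic intervals are 0-based half-open (BED convention) internally;
mutation positions are 1-based on input and converted on read. Strand is
`+`, `-` or `.`. The overlap predicate everywhere is "at least one shared
base" on half-open intervals.

## Lesion calling

CPD-seq chemistry converts each dimer into a ligatable 3′ end on the
damaged strand, so a read documents the lesion *behind* its 5′ end:

* plus-strand read with 5′ end at `s` — plus-strand window `[s-2, s)`,
  lesion is its reverse complement on the minus strand over `[s-2, s)`;
* minus-strand read with 5′ end at `e` — window maps to plus-strand
  interval `[e+1, e+3)`, lesion on the plus strand.

Both positions of the dimer count as lesion sites in integer-resolution
profiles. Non-dipyrimidine windows are background (incomplete 3′ blocking
or nonspecific cleavage) and are excluded; windows containing N and
windows off the chromosome edge are rejected under separate counters, so
every input read is accounted for exactly once. Mutagenic CPDs (mCPDs)
are the cytosine-containing classes TC, CT, CC.

The test suite pins this logic to a brute-force oracle: an independent
character-level implementation is evaluated at every possible read
placement on a 1-kb genome and must agree exactly, including rejection
reasons, plus a mirror-symmetry property under genome reverse complement.

## XR-seq localization

Excision repair releases ~24–30-nt oligomers with the lesion at a fixed
register from the 3′ end. For offsets `o = 6, 7, 8`, in that order, the
dinucleotide whose 3′ base lies `o` bases upstream of the 3′-terminal base
(read-strand coordinates) is tested; the first dipyrimidine wins, and
reads without one are excluded. "o bases upstream" is implemented
exclusively of the terminal base (3′ base of the candidate at read index
`L-1-o`); the one-base-shifted alternative reading is available via
`terminal_inclusive = TRUE`. The first-hit rule means a decoy dipyrimidine
at a smaller offset shadows the true lesion; the generator's truth tables
let tests document exactly this behaviour (recovery is exact in decoy-free
settings, and recovered offsets never exceed planted ones otherwise).

## TFBS curation and midpoints

The curation cascade is: keep known-motif sites only; merge overlapping
same-TF sites (interval union); flag promoter overlap
(`promoter_proximal`); flag DNase-hypersensitivity overlap among
promoter-proximal sites (`active`); drop blacklist overlaps. Promoter
windows are supplied as intervals rather than recomputed from gene models
so any TSS catalog can be plugged in.

Midpoints average the *inclusive* first and last base, `(start + end-1)/2`
— chosen over the half-open mean because an odd-length site then has an
exact central base — rounding up when fractional (`simple` mode), or up
on `+` and down on `-` strands (`strand_aware` mode, used for the
high-resolution ETS analysis). When several sites share `(chrom,
midpoint)` only the first instance in input order is kept, so aggregated
profiles count each aligned position once.

## ETS alignment

ETS sites are aligned on the TTCC core so that profiles from different
motif variants superimpose. Offset 0 is the **first C of the central CC**
(the third base of TTCC): the lesion-forming TC step then spans offsets
−1/0 and the CC step 0/+1, and the canonical `CTTCCGG` consensus occupies
offsets −3..+3. This anchor is the one consistent with the damage
signature's step labels and with the mutated core C being "position 0";
it is encoded in `ets_catalog()` as `anchor_offset = 3` and verified in
the tests by checking that the sequence at offsets −1..+1 of an aligned
site reads `TCC`. Orientation is the strand carrying TTCC; minus-strand
sites mirror their offsets.

## Profiles and damage enrichment

`position_profile()` averages lesion counts per site at each offset in
`[-W, +W]` (default `W` = 100 bp). Integer resolution credits both lesion
bases (+1 each); fractional resolution credits the half-integer midpoint
of the step (a lesion at bases 50/51 appears at 50.5), which keeps each
dipyrimidine step a single, unsplit observation. Lesion strands are
combined, as pyrimidine content on the two strands is anticorrelated and
strand-resolved profiles would confound sequence composition with
biology. A lesion straddling the window edge contributes only its
in-window base in integer mode and is dropped in fractional mode.

Sequencing depth differs between the cellular and naked-DNA libraries, so
raw ratios are scaled by `f`, the ratio of total lesion counts in
promoter-proximal territory; after scaling, promoter territory has
enrichment exactly 1 (asserted at 1e-12). The per-TF statistic is

```
core_enrichment  = (core_cells / core_naked) / f      core  = -4..+4
flank_enrichment = (flank_cells / flank_naked) / f    flank = |5|..|100|
```

on per-base in-window counts. The scalar `total_core_lesions` (the x-axis
quantity for ranking TFs by damage burden) counts whole lesions, with a
step straddling the core boundary (−5/−4 or +4/+5) counted 0.5 — the
half-weight applies to this scalar only, not to the enrichment ratio,
which stays a pure per-base count ratio. TFs with fewer than 5 core
counts in either dataset are flagged `included = FALSE` rather than
dropped.

Whole-core enrichment dilutes a hotspot confined to one or two steps; the
sharper estimator for a planted step is the fractional-profile ratio at
that half-integer offset (`profile_enrichment()`), which the recovery
tests use to check injected folds of 2/5/16 to within 20%.

## Trinucleotide mutation model

UV mutagenesis is strongly context-dependent, so the expected mutation
density is modelled by 32 pyrimidine-centered trinucleotide rates:
`rate(c) = mutations at c / occurrences of c` within an estimation
territory (typically the promoter windows). Purine-centered mutations
fold to the pyrimidine strand by reverse complement; every position
contributes through exactly one folded context. 32 contexts rather than
96 substitution-typed channels: the expectation needs position-level
rates only, not per-alt rates (a stranded 64-context variant would add
parameters without changing position-level expectations, since each
position's two strand readings are the same folded context). Positions at
territory edges lacking a full trinucleotide inside the interval are
excluded from numerator and denominator alike; overlapping territory
intervals are reduced to a disjoint set before counting.

Because the rates are a ratio estimator fitted on the same territory, the
expected total over that territory equals the observed total *exactly*
(an algebraic identity, asserted at 1e-9). Per-TF mutation enrichment is
`observed_core / expected_core` over offsets −4..+4 of deduplicated
sites, with inclusion requiring at least 1 observed core mutation and at
least 50 sites. Note one behaviour worth knowing: a strong planted
hotspot inflates the fitted rate of its own context (the hotspot
mutations enter the signature numerator), so observed/expected at the
hotspot under-reports the injected fold — the recovery test therefore
checks peak *location* and peak/off-peak separation, not the raw fold.

`rank_correlation()` (damage vs mutation enrichment across TFs) uses
average ranks for ties, an exhaustive-permutation two-sided p for n ≤ 9
(pinned in tests against an independent enumerator and `cor.test`), and
the t-approximation above that.

## Metagene profiles

Genes are stratified into expression quartiles (type-7 percentiles,
boundary values to the lower quartile) and split into 6 fractional
gene-body bins (lengths within 1 base) plus flank bins; "two 5000-bp
bins upstream and downstream" is read as two bins on each side (the
alternative is a parameter, `flank_bins_per_side`). Lesions are assigned
by the genomic position of their 5′ base on the lesion strand — a
deterministic single-bin assignment — and classified transcribed
(template; opposite the gene strand) or non-transcribed. Mutations are
assigned by position, with strand taken from the pyrimidine member of the
mutated pair. Counts are normalized by the per-bin, per-strand number of
overlapping dipyrimidine occurrences ("TTT" = 2), counted with the same
5′-base bin assignment, so a uniform lesion field yields a normalized
profile that is exactly flat (asserted in tests), and mirror symmetry
under reverse complement is exact.

## Dipyrimidine step geometry

CPD formation requires the C5–C6 double bonds of adjacent pyrimidines to
be close (d < 4 Å) and favourably aligned (η ~ 20–30°). For a step:

* `d` — distance between the midpoints of the two C5–C6 bonds;
* `η` — absolute four-atom torsion of the chain C5(5′)–C6(5′)–C6(3′)–C5(3′),
  reported in [0°, 180°].

The atom-chain convention for η is not uniquely fixed by the literature;
the alternative chain C6–C5–C5–C6 is available via `convention =`. The
default is frozen as stated; confirming it against the published
crystal-structure means requires the ETS1–DNA PDB entries, which cannot
be redistributed with the package — the acceptance test encodes that
comparison and runs whenever the files are placed under
`inst/extdata/pdb/`. Both quantities are rigid-motion invariant and
symmetric under 5′/3′ relabelling (η as an absolute value), asserted
numerically.

`scan_structure()` walks an ordered strand, taking steps only between
consecutive pyrimidines with complete C5/C6 atoms (incomplete steps are
skipped and counted); offsets are labelled relative to a motif anchor,
with `step = -1` for the complementary strand. Multi-model PDB files
contribute their first model only; alternate locations resolve by highest
occupancy, then altLoc "A". Trajectory post-processing takes a plain
per-frame coordinate table (`trajectory_geometry()`); histograms use
left-closed right-open bins anchored at 0 (0.05 Å / 1° are the
conventional widths), with a 1e-9 relative epsilon so boundary-printed
values land in the right-hand bin.

The geometry oracle is an idealized helix (`gen_bdna()`): C5/C6 atoms
placed by rotation `twist` and translation `rise` per base, with `d` from
the closed form `sqrt(4 sin^2(twist/2) |m_xy|^2 + rise^2)` and `η` from a
plane-normal dihedral formulation independent of the package's atan2
implementation; a further cross-check uses `bio3d::torsion.xyz`.
Agreement is required at 1e-6 over random (rise, twist) settings.

## What the synthetic generator emulates — and what it does not

The generators are first-class, tested code and define the study
conditions for all recovery tests:

* genomes are i.i.d. bases at a set GC fraction (default 0.4, roughly
  mammalian); no repeats, isochores or chromatin structure;
* planted motifs are exact `CTTCCGG` copies on random strands with a
  controllable fraction (default 0.12) carrying a pyrimidine at offset −4,
  mirroring the minority of real ETS sites able to form the −4/−3 CPD;
* lesion sampling weights follow the qualitative photoreactivity ordering
  TT:1.0 > TC=CT:0.6 > CC:0.3 (free parameters, not measured values),
  times a per-step fold map applied only in the "cells" dataset — the
  naked-DNA control shares the sequence pool but ignores folds, exactly
  the contrast the enrichment statistic assumes;
* each simulated lesion is emitted as the read-end record that
  `call_cpd()` inverts to it, making round-trips exact by construction;
* mutations are drawn position-wise from a trinucleotide signature times
  hotspot folds, with uniform alt bases and round-robin donors (184 by
  default, the cohort size convention used throughout); no selection,
  clonality or regional mutation-rate covariates.

Passing recovery tests therefore demonstrates the estimators' correctness
and calibration under these idealized conditions — not robustness to
mappability artifacts, chromatin covariates or signature
misspecification in real data.

One scale caveat: at toy scale, planted cores are a far larger fraction
of the genome than real TFBS are of promoter territory, so a
whole-territory scale factor would absorb part of a strong planted
elevation. Recovery tests that inject core-wide folds therefore compute
`f` on territory at least 50 bp away from any planted site, which is the
regime the statistic faces in real data (binding-site cores are a
vanishing fraction of promoters).

## Problem sizes and determinism

Recovery tests run at 4e5–1e6-bp genomes, 1000 sites and 1e5–2e5 reads
per dataset; null calibrations use 50 replicates at 1e5 bp / 200 sites.
These sizes keep each statistic's sampling error well inside the bands
being asserted. Every generator is a deterministic function of its
parameters and an explicit seed, with the RNG state restored afterwards
(`with_seed`), so fixtures never leak randomness across tests; the
acceptance script derives all sub-seeds from its `--seed` flag.

## Known limitations

* Single-interval genes (no isoforms) and no transcription-coupled-repair
  modelling in the metagene module.
* Only CPDs are modelled; 6-4 photoproducts are out of scope.
* The mutation model is position-level; it does not type substitutions
  (no 96-channel deconvolution) and assumes donor-level deduplication has
  been applied (`dedupe_donor_mutations()` is provided).
* `ets_structure_steps()` scans motif-bearing chains; complementary-chain
  steps require an explicit strand specification to `scan_structure()`
  because base-pairing registers are not inferred from coordinates.
* The η atom-chain convention awaits confirmation against the published
  structural means (see above); both conventions are exposed.
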