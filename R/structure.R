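# CPD-formation geometry: distance d between the midpoints of adjacent
# C5-C6 bonds and torsion angle eta between those bonds, from static
# structures and trajectory frames.

NUCLEOTIDE_RESIDUES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "T", "U", "DU")
PYRIMIDINE_RESIDUES <- c("DC", "DT", "C", "T", "U", "DU")

#' Read atoms from a PDB file
#'
#' Parses ATOM/HETATM records of the first MODEL into a tibble. Alternate
#' locations are resolved per (chain, residue, atom) by highest occupancy,
#' then altLoc "A".
#'
#' @param path path to a PDB file.
#' @return tibble: `chain`, `resno`, `resid`, `elety` (atom name), `x`, `y`,
#'   `z` (Angstrom), `occupancy`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # keep only the first MODEL when the file holds several
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) {
    lines <- lines[seq_len(endm[1] - 1L)]
    path <- tempfile(fileext = ".pdb")
    writeLines(c(lines, "END"), path)
    on.exit(unlink(path), add = TRUE)
  }
  if (!any(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))) {
    abort("no ATOM records in PDB file")
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) abort("no ATOM records in PDB file")
  df <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o)
  )
  df |>
    dplyr::group_by(.data$chain, .data$resno, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$occupancy),
                   .data$alt != "A", .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"alt")
}

#' Look up one atom in a structure
#'
#' @param atoms tibble from [read_structure()].
#' @param chain,resno,elety atom address.
#' @return one-row tibble, or a zero-row tibble when the atom is absent
#'   (never a silent zero coordinate).
#' @export
structure_atom <- function(atoms, chain, resno, elety) {
  atoms[atoms$chain == chain & atoms$resno == resno & atoms$elety == elety, ]
}

# Unsigned dihedral (degrees, [0, 180]) of the 4-point chain p1-p2-p3-p4,
# computed with the atan2 ("praxeolitic") formulation.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  abs(ang)
}

#' Geometry of one dipyrimidine step
#'
#' Computes the two determinants of CPD photoreactivity for a pair of
#' adjacent same-strand pyrimidines: `d`, the distance between the midpoints
#' of the two C5-C6 bonds, and `eta`, the absolute torsion angle of the
#' four-atom chain C5(5')-C6(5')-C6(3')-C5(3') (the alternate chain
#' C6-C5-C5-C6 is available via `convention`). Both are invariant under
#' rigid-body motion.
#'
#' @param C5a,C6a,C5b,C6b numeric length-3 coordinates (Angstrom) of the 5'
#'   (a) and 3' (b) pyrimidine C5/C6 atoms.
#' @param convention `"C5-C6-C6-C5"` (default) or `"C6-C5-C5-C6"`.
#' @return tibble with `d` (Angstrom) and `eta` (degrees in `[0, 180]`).
#' @examples
#' step_geometry(c(0, 0, 0), c(2, 0, 0), c(0, 0, 3.4), c(2, 0, 3.4))
#' @export
step_geometry <- function(C5a, C6a, C5b, C6b,
                          convention = c("C5-C6-C6-C5", "C6-C5-C5-C6")) {
  convention <- match.arg(convention)
  pts <- rbind(C5a, C6a, C5b, C6b)
  if (any(!is.finite(pts))) abort("step_geometry: non-finite coordinates")
  dm <- as.matrix(stats::dist(pts))
  if (any(dm[upper.tri(dm)] < 1e-9)) abort("step_geometry: coincident atoms")
  d <- sqrt(sum(((C5a + C6a) / 2 - (C5b + C6b) / 2)^2))
  eta <- if (convention == "C5-C6-C6-C5") {
    dihedral4(C5a, C6a, C6b, C5b)
  } else {
    dihedral4(C6a, C5a, C5b, C6b)
  }
  tibble(d = d, eta = eta)
}

#' Scan a structure strand for dipyrimidine steps
#'
#' Walks an ordered strand (5'->3') of residue numbers in one chain and
#' computes [step_geometry()] for every pair of consecutive pyrimidines.
#' Steps missing a C5 or C6 atom are skipped and counted. Motif offsets are
#' assigned relative to an anchor residue: residue at index i gets offset
#' `anchor_offset + step * (i - index(anchor))`, so the complementary strand
#' can be scanned in motif orientation with `step = -1`.
#'
#' @param atoms tibble from [read_structure()].
#' @param chain chain identifier.
#' @param resno_order residue numbers in 5'->3' strand order.
#' @param anchor_resno residue number given motif offset `anchor_offset`
#'   (optional; offsets are NA without it).
#' @param anchor_offset motif offset of the anchor residue (default 0).
#' @param step offset increment per residue along `resno_order` (+1 on the
#'   motif strand, -1 on its complement).
#' @param convention dihedral atom-chain convention, see [step_geometry()].
#' @return tibble: `chain`, `resno5`, `resno3`, `resid5`, `resid3`,
#'   `offset5`, `offset3`, `offset_label` ("min/max"), `d`, `eta`; attribute
#'   `"skipped_missing_atoms"`.
#' @export
scan_structure <- function(atoms, chain, resno_order, anchor_resno = NULL,
                           anchor_offset = 0L, step = 1L,
                           convention = "C5-C6-C6-C5") {
  ats <- atoms[atoms$chain == chain, ]
  resid_of <- function(r) {
    x <- unique(ats$resid[ats$resno == r])
    if (length(x) == 0L) NA_character_ else x[1]
  }
  offs <- if (!is.null(anchor_resno)) {
    ai <- match(anchor_resno, resno_order)
    if (is.na(ai)) abort("scan_structure: anchor residue not in resno_order")
    anchor_offset + step * (seq_along(resno_order) - ai)
  } else {
    rep(NA_integer_, length(resno_order))
  }
  out <- list(); skipped <- 0L
  for (i in seq_len(length(resno_order) - 1L)) {
    r5 <- resno_order[i]; r3 <- resno_order[i + 1L]
    res5 <- resid_of(r5); res3 <- resid_of(r3)
    if (is.na(res5) || is.na(res3)) next
    if (!(res5 %in% PYRIMIDINE_RESIDUES && res3 %in% PYRIMIDINE_RESIDUES)) next
    coords <- lapply(list(c(r5, "C5"), c(r5, "C6"), c(r3, "C5"), c(r3, "C6")),
                     function(a) {
                       row <- structure_atom(ats, chain, as.integer(a[1]), a[2])
                       if (nrow(row) == 0L) NULL else c(row$x, row$y, row$z)
                     })
    if (any(vapply(coords, is.null, logical(1)))) { skipped <- skipped + 1L; next }
    g <- step_geometry(coords[[1]], coords[[2]], coords[[3]], coords[[4]],
                       convention = convention)
    o <- sort(c(offs[i], offs[i + 1L]))
    out[[length(out) + 1L]] <- tibble(
      chain = chain, resno5 = r5, resno3 = r3, resid5 = res5, resid3 = res3,
      offset5 = o[1], offset3 = o[2],
      offset_label = if (all(is.finite(o))) paste(o[1], o[2], sep = "/")
                     else NA_character_,
      d = g$d, eta = g$eta
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble(
    chain = character(), resno5 = integer(), resno3 = integer(),
    resid5 = character(), resid3 = character(), offset5 = integer(),
    offset3 = integer(), offset_label = character(), d = numeric(),
    eta = numeric())
  attr(res, "skipped_missing_atoms") <- skipped
  res
}

#' Scan every TTCC-bearing DNA chain of a structure
#'
#' Convenience wrapper for ETS-bound structures: for each chain containing
#' nucleotide residues, the base sequence is reconstructed in residue-number
#' order and searched for the TTCC core; chains carrying it are scanned with
#' the anchor (motif offset 0) at the first C of the central CC. Chains
#' without the core are skipped.
#'
#' @param atoms tibble from [read_structure()].
#' @param convention dihedral convention, see [step_geometry()].
#' @return combined [scan_structure()] tibble over all motif-bearing chains.
#' @export
ets_structure_steps <- function(atoms, convention = "C5-C6-C6-C5") {
  base_of <- c(DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
               A = "A", C = "C", G = "G", T = "T", U = "U")
  out <- list()
  for (ch in unique(atoms$chain)) {
    res <- atoms[atoms$chain == ch & atoms$resid %in% NUCLEOTIDE_RESIDUES, ] |>
      dplyr::distinct(.data$resno, .data$resid) |>
      dplyr::arrange(.data$resno)
    if (nrow(res) < 4L) next
    seq <- paste(base_of[res$resid], collapse = "")
    hit <- regexpr("TTCC", seq, fixed = TRUE)[1]
    if (hit < 0) next
    anchor <- res$resno[hit + 2L]  # first C of the central CC
    out[[length(out) + 1L]] <- scan_structure(atoms, ch, res$resno,
                                              anchor_resno = anchor,
                                              convention = convention)
  }
  if (!length(out)) abort("ets_structure_steps: no chain carries the TTCC core")
  dplyr::bind_rows(out)
}

#' Summarize step geometry by motif offset
#'
#' @param steps tibble from [scan_structure()] (rows from several structures
#'   may be bound together).
#' @return a `geometry_summary` tibble per `offset_label`: `n`, `d_mean`,
#'   `d_sem`, `eta_mean`, `eta_sem` (SEM = sd/sqrt(n), sd with n-1
#'   denominator; 0 with `single_value = TRUE` when n = 1).
#' @export
summarize_geometry <- function(steps) {
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  out <- steps |>
    dplyr::group_by(.data$offset_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      d_mean = mean(.data$d), d_sem = sem(.data$d),
      eta_mean = mean(.data$eta), eta_sem = sem(.data$eta),
      single_value = dplyr::n() == 1L,
      .groups = "drop"
    )
  structure(out, class = c("geometry_summary", class(out)))
}

#' Fixed-width histogram of distances or angles
#'
#' Left-closed, right-open bins anchored at 0 (a value exactly on a
#' boundary goes to the right bin); the total count equals the input
#' length.
#'
#' @param values numeric vector (e.g. per-frame distances or dihedrals).
#' @param bin_width bin width (e.g. 0.05 for Angstrom, 1 for degrees).
#' @return tibble: `bin_start`, `bin_end`, `count`.
#' @export
bin_series <- function(values, bin_width) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("bin_series: bin_width must be positive")
  }
  # small relative epsilon so values printed on a boundary (3.45 at width
  # 0.05) land in the right-hand bin despite binary rounding
  idx <- floor(values / bin_width + 1e-9)
  tb <- table(idx)
  tibble(
    bin_start = as.numeric(names(tb)) * bin_width,
    bin_end = (as.numeric(names(tb)) + 1) * bin_width,
    count = as.integer(tb)
  )
}

#' Per-frame step geometry from a trajectory coordinate table
#'
#' Post-processes a plain per-frame atom-coordinate table (one row per
#' frame/atom) into per-frame (d, eta) series for one dipyrimidine step.
#'
#' @param traj tibble with columns `frame`, `atom` (one of "C5a", "C6a",
#'   "C5b", "C6b"), `x`, `y`, `z`.
#' @param convention dihedral convention, see [step_geometry()].
#' @return tibble: `frame`, `d`, `eta`.
#' @export
trajectory_geometry <- function(traj, convention = "C5-C6-C6-C5") {
  need <- c("C5a", "C6a", "C5b", "C6b")
  traj |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_modify(function(df, key) {
      if (!all(need %in% df$atom)) abort("trajectory_geometry: missing atom in frame")
      p <- lapply(need, function(a) {
        r <- df[df$atom == a, ][1, ]
        c(r$x, r$y, r$z)
      })
      step_geometry(p[[1]], p[[2]], p[[3]], p[[4]], convention = convention)
    }) |>
    dplyr::ungroup()
}
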