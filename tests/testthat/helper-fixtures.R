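# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files the helpers write to tempdir().

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

dna <- function(..., names = NULL) {
  x <- Biostrings::DNAStringSet(c(...))
  if (!is.null(names)) names(x) <- names
  x
}

empty_mutations <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), donor = character())
}

# Independent character-level re-implementation of the CPD calling rule,
# used as the brute-force oracle: enumerate a read placement and derive the
# lesion by complementing bases one at a time.
oracle_cpd <- function(seq_chars, five_prime, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  L <- length(seq_chars)
  if (strand == "+") {
    if (five_prime - 2 < 0) return(list(reason = "edge"))
    b <- seq_chars[(five_prime - 1):five_prime]  # 1-based: 0-based s-2, s-1
    lesion_start <- five_prime - 2
    lesion_strand <- "-"
    dinuc <- paste0(comp[b[2]], comp[b[1]])      # 5'->3' on the minus strand
  } else {
    if (five_prime + 3 > L) return(list(reason = "edge"))
    b <- seq_chars[(five_prime + 2):(five_prime + 3)]  # 0-based e+1, e+2
    lesion_start <- five_prime + 1
    lesion_strand <- "+"
    dinuc <- paste0(b[1], b[2])
  }
  if (any(b == "N")) return(list(reason = "ambiguous_base"))
  if (!dinuc %in% c("TT", "TC", "CT", "CC")) return(list(reason = "non_dipyrimidine"))
  list(start = lesion_start, strand = lesion_strand, dinuc = dinuc)
}

# Write a minimal but column-correct PDB file from an atom table.
write_test_pdb <- function(atoms, path, extra_model = FALSE) {
  fmt <- function(i, a) {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
            i, paste0(" ", a$elety), a$alt %||% " ", a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$occupancy %||% 1, 0, substr(a$elety, 1, 1))
  }
  lines <- vapply(seq_len(nrow(atoms)),
                  function(i) fmt(i, as.list(atoms[i, ])), character(1))
  if (extra_model) {
    shifted <- atoms
    shifted$x <- shifted$x + 100
    lines2 <- vapply(seq_len(nrow(shifted)),
                     function(i) fmt(i, as.list(shifted[i, ])), character(1))
    lines <- c("MODEL     1", lines, "ENDMDL", "MODEL     2", lines2, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
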