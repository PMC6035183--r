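Package: cpdseqr
Title: UV Damage and Mutation Analysis at Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls cyclobutane pyrimidine dimer (CPD) lesions from CPD-seq
    read ends, localizes repair events in XR-seq reads, curates transcription
    factor binding site (TFBS) sets, and quantifies UV damage and somatic
    mutation enrichment at binding sites with a naked-DNA-scaled damage
    statistic and a trinucleotide observed/expected mutation model. Includes
    strand-resolved metagene profiles across expression quartiles, the
    dipyrimidine C5-C6 distance/torsion geometry that underlies CPD
    photoreactivity, and a synthetic-data generator with truth tables for
    end-to-end recovery testing. All user-facing functions take and return
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
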