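Package: mapanchor
Title: Genetic-Map Anchoring of Draft Genome Scaffolds into Pseudomolecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building chromosome-scale pseudomolecules from a
    fragmented draft assembly and a SNP linkage map: marker binning, scaffold
    anchoring, detection and splitting of chimeric (multi-position) scaffolds,
    orientation by rank correlation of physical and genetic positions,
    deterministic ordering, and AGP/FASTA emission with fixed N gaps. Also
    provides Table-1-style assembly summaries (N50, GC%, completeness),
    k-mer-histogram genome-size estimation, reciprocal-best-hit gene pairing,
    synteny dot-plot coordinates, Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
    correction, Ks histograms, calibrated divergence-time scaling of
    phylogenetic trees, and a seeded synthetic-genome simulator with truth
    tables for recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    seqinr,
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
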