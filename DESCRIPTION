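Package: neocenscan
Title: Neocentromere Discovery from CENH3 ChIP-Seq Scaffold Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of de novo centromere (neocentromere) sequences from
    CENH3 ChIP-seq in fragmented genome assemblies. Implements repeat-aware
    paired-end read placement with random assignment of multi-mapping reads,
    fragment-level PCR duplicate removal, per-scaffold reads-per-million (RPM)
    normalization, a two-branch differential scaffold selection rule
    (RPM ratio over a control sample, or treatment-only read count),
    candidate-region assembly with GC/gene/repeat annotation, a seed-and-extend
    ungapped homology search for cross-genome confirmation, and a synthetic
    data generator that plants a neocentromere in a fragmented repeat-rich
    genome so that the whole pipeline can be validated against known truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
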