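Package: epcquant
Title: Strain-Level Metabarcoding Quantification of Early Partner Choice in
    Rhizobium-Legume Symbiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying early partner choice (EPC) of rhizobia on
    legume roots by strain-discriminating amplicon metabarcoding. Covers
    barcode window design over a marker-gene alignment, exact-match read
    processing (pair merging, demultiplexing, primer trimming, expected-error
    tracking, dereplication, chimera QC, strict allele assignment), the EPC
    index with replicate statistics and profile clustering, nonparametric
    genotype-phenotype association (Kruskal-Wallis with Dunn post hoc),
    top-versus-bottom gene presence/absence contrasts with a seed-and-extend
    presence check and bidirectional best hits, fragment-based average
    nucleotide identity with genospecies clustering, neighbor-joining on
    concatenated nodulation genes, and repABC-based replicon classification.
    A synthetic-data module generates complete ground-truth study designs
    (strain panels, pangenomes with planted effects, host-specific mixtures,
    error-bearing paired FASTQ) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
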