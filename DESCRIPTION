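Package: syntevol
Title: Conserved Synteny, Substitution Rates and Divergence Dating for
    Homologous Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of homologous genomic regions in grasses
    and other plants: detection of pairwise conserved blocks with
    conserved-sequence-ratio (CSR) and average conserved-fragment-size (CFS)
    statistics, classification of inter-block gaps into transposable-element
    insertions and deletions, detection of conserved non-coding sequences
    (CNS) shared by two or more regions, cis-regulatory motif and
    microsatellite (SSR) scanning, Kimura two-parameter nucleotide distances,
    Nei-Gojobori Ka/Ks estimation, LTR-retrotransposon insertion dating via
    T = K/2r, calibrated molecular-clock divergence times, and
    neighbor-joining phylogenies with bootstrap support. A synthetic-data
    generator produces homologous region pairs and trios with known ground
    truth (substitution divergence, lineage-specific TE insertions, embedded
    genes under purifying selection, SSRs, promoter motifs and shared
    non-coding segments) so that every estimator can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    ape,
    data.table,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
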