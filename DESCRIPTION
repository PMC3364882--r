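Package: straincomp
Title: Comparative Analysis of Assembled Strain Genomes Against a Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing a de novo assembled microbial genome
    against an annotated reference: anchor-based whole-genome alignment
    with maximal-exact-match seeding and chaining, SNV and small-indel
    calling with gene-effect annotation, depth-of-coverage log2-ratio
    copy-number analysis with a Geary-Hinkley ratio test, assembly-gap
    and LTR-retrotransposon locus classification, gene presence/absence
    and unique-region detection with a cross-strain conservation screen,
    mosaic genome painting against grouped strain panels, coverage-distance
    UPGMA phylogenies, and EASE-score category enrichment. Includes a
    synthetic genome-pair simulator that plants SNVs, indels, deletions,
    duplications, transposon excisions and novel insertions with a full
    truth table, so every stage of the pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    vcfR
Config/testthat/edition: 3
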