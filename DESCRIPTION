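Package: actghap
Title: Hierarchical ACTG Haplotype Nomenclature for Gene-Level Phased Assemblies
Version: 1.0.0
Authors@R: person("actghap", "maintainers", email = "actghap@example.org",
    role = c("aut", "cre"))
Description: Derives protein (A), coding (C), exonic non-coding (T) and
    intronic (G) haplotype sequences of a gene from phased long-read contig
    alignments or phased variant tables, filters variants with a
    homopolymer-calibrated binomial variant quality value (VQV), assigns
    globally frequency-ranked haplotype identifiers with reference
    assemblies embedded in the same ranking, and computes catalog diversity
    statistics (Good-Turing coverage, Chao1 completeness, subsampled
    haplotype counts) and diplotype-based haplotype-expression QTL
    associations with cross-study concordance. Includes a fully seeded
    synthetic-data module that generates every input format the pipeline
    consumes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
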