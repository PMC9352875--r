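Package: graphref
Title: Population-Specific Genome Graph Reference Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing population-specific genome graph
    references: nucleotide diversity and absolute divergence of a
    population relative to a linear backbone reference, a binomial model
    of graph representativeness (true/false positive rates of variant
    selection as a function of the number of construction samples), and a
    staged graph construction pipeline covering variant harmonization
    (multiallelic splitting, left normalization, allele-frequency
    filtering), alt-contig decomposition into variant paths,
    structural-variant ambiguity filtering with decoy masking, and
    multi-mapping pruning via exhaustive read simulation. Includes a
    synthetic-data generator (reference contigs, diploid populations
    drawn from an allele-frequency density, structural-variant call
    sets) so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    graphics,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
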