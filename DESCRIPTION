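Package: RMscout
Title: Discovery and Defeat of Bacterial Restriction-Modification Barriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for characterising and defeating bacterial
    restriction-modification (RM) barriers to plasmid transformation.
    Provides IUPAC degenerate motif scanning on both strands of linear or
    circular DNA, inference of (possibly bipartite Type I) recognition motifs
    from N6-methyladenine position calls against a genome, synonymous
    ("silent") recoding of coding sequences to ablate or create recognition
    sites or to scrub every possible site of a given length, localization of
    a restriction-sensitive region from panels of deletion-derivative
    constructs with measured transformation efficiencies, and simulators that
    generate SMRT-style methylomes and construct panels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
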