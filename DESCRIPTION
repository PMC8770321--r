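Package: riboNterm
Title: Riboproteogenomic Discovery of N-Terminal Proteoforms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls translation initiation sites (TIS) from paired
    lactimidomycin (LTM) and cycloheximide (CHX) ribosome-profiling
    P-site tracks, builds a proteoform search database from called TIS,
    classifies N-terminal peptide evidence using the enzymatic rules of
    initiator-methionine excision (NME) and N-terminal acetylation (NTA),
    quantifies NTA stoichiometry from light/heavy acetyl precursor pairs,
    and resolves transit-peptide cleavage versus downstream-TIS origins of
    protein N-termini. Ships a seeded synthetic-data generator that plants
    TIS, proteoforms, cleavage sites and acetylation degrees with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: RiboSeq, Proteomics, Proteogenomics, Coverage, Annotation
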