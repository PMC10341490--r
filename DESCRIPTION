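Package: VHHscreen
Title: Screening Tumor-Specific VHH Antibodies from Phage-Display Panning Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying candidate tumor-specific VHH (nanobody)
    binders from high-throughput sequencing of phage-display panning rounds.
    Paired-end amplicon reads are merged, quality-filtered, primer-trimmed and
    translated into VHH amino-acid clonotypes; clones are ranked by their
    amplification fold between the unselected round-0 library and the final
    panning round; top-ranked clones are placed on neighbor-joining trees
    built from pairwise alignment distances; and candidate binders are called
    mono-specific or cross-reactive from cluster library composition and
    identical-CDR3 sharing across libraries. A ground-truthed panning
    simulator generates error-bearing paired-end FASTQ so the whole pipeline
    is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
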