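Package: sedimotu
Title: Metabarcoding of Deep-Sea Sediment Communities from eDNA and eRNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of an 18S rRNA (v7) metabarcoding
    workflow for deep-sea sediment communities: paired-end merging, tag-based
    demultiplexing with chimera elimination, dereplication, similarity
    cleaning against a reference database, flexible-threshold MOTU clustering,
    best-hit/LCA taxonomic assignment, cumulative-frequency contamination
    filtering, and presence/absence multivariate statistics (Jaccard,
    PERMANOVA, PERMDISP, nMDS, environmental vector fitting, rarefaction).
    Includes a synthetic-data module that emulates a stratified sediment
    sampling design (stations x corers x layers x seasons, DNA/RNA
    co-extraction, blanks and negative controls) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    yaml
Config/testthat/edition: 3
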