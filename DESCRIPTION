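Package: alncons
Title: Residue Conservation, Clade Conservation Bias, and Two-Domain
    Homolog Classification for Protein Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the molecular evolution of two-domain
    proteins such as insect Oskar from protein multiple sequence
    alignments. Implements per-column conservation statistics (the Valdar
    weighted sum-of-pairs score, a windowed Jensen-Shannon divergence
    score, electrostatic and hydrophobicity conservation, aggregation of
    per-sequence RNA-binding propensity and secondary-structure tracks),
    a bootstrapped between-clade conservation-bias statistic, multiple
    correspondence analysis of alignment sequence space, and the
    domain-architecture rules that define a homolog (ordered domain hits
    under an E-value cutoff, per-taxon isoform deduplication by percent
    identity, and within-species duplication flagging). Includes a
    synthetic-alignment generator with plantable per-column and per-clade
    conservation for testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
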