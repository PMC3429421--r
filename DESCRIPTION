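Package: sinephylo
Title: Dollo Parsimony Phylogenetics for SINE Presence/Absence Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building phylogenies from retrotransposon (SINE/Alu)
    presence/absence characters. Provides I/O for binary character matrices
    (CSV and NEXUS with Dollo character-type assumptions), Dollo parsimony
    scoring with ancestral gain/loss reconstruction and ensemble indices
    (CI, HI, RI), heuristic most-parsimonious tree search with outgroup
    rooting, bootstrap and consensus, an exact trinomial likelihood test for
    per-branch insertion support, an in-silico screening stage for candidate
    lineage-specific elements from RepeatMasker annotations, and seeded
    generators for insertion histories with confounding events. Includes a
    24-taxon lemur Alu fixture matrix reconstructed from published per-clade
    locus counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
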