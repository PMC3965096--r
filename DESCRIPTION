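Package: nipr
Title: Derivation of Non-Interacting Protein and Domain Pairs from
    Structural Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects non-interacting protein chain pairs inside
    multi-chain biological assemblies using a strict minimum
    C-beta--C-beta (C-alpha for glycine) distance rule, consolidates
    chain-level results into protein-level non-interacting pair (NIP)
    records, expands protein pairs into Pfam domain pairs, filters
    candidate sets against known protein-protein (PSI-MI TAB) and
    domain-domain interaction catalogues to produce stringent negative
    reference datasets, merges structure-derived and curated datasets
    with overlap accounting, and scores negated-interaction candidates
    extracted from text as predicate-argument structures.  Seeded
    fixture generators make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
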