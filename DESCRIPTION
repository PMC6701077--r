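Package: groupfrag
Title: Automatic Molecule Fragmentation into Group-Contribution Functional Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragments molecules given as SMILES strings into non-overlapping
    functional-group assignments for group-contribution modelling (UNIFAC-style
    schemes defined as SMARTS patterns). Implements a fast heuristic fragmenter
    that prioritizes patterns by a descriptor sort, parent-child pattern
    containment and adjacency-constrained retries, and an exhaustive
    exact-cover tree search that enumerates and ranks every valid
    fragmentation. Ships the full UNIFAC fragmentation scheme, a brute-force
    cover-enumeration oracle, deterministic fixture generators for homologous
    series, and tooling to compare fragmentations against a reference database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
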