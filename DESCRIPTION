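Package: globinCensus
Title: Globin Identification, Classification and Census in Fungal Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a genome-scale census of globins in fungal proteomes.
    Candidate proteins are validated against the myoglobin-fold checklist of
    conserved solvent-inaccessible hydrophobic positions with a shuffle-null
    Z-score, classified by domain architecture into the flavohemoglobin (F),
    sensor (S) and truncated 2/2 (T) globin families and their subfamilies,
    and trimmed to the globin domain. Alternative multiple alignments of the
    same sequences are ranked by a pairwise overlap score, neighbor-joining
    trees are built from Poisson-corrected distances with pairwise deletion
    and bootstrap supports, and per-genome inventories are aggregated into
    taxon-grouped presence counts and ratios. A synthetic proteome generator
    with planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
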