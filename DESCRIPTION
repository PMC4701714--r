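Package: migsphase
Title: Phase-Register Analysis of MIGS-Derived Small RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing miRNA-induced gene silencing (MIGS) from
    small RNA sequencing libraries. Reads and collapses small RNA libraries,
    maps tags to a MIGS expression cassette, miRNA stem-loop precursor and
    endogenous homologs by exact matching on both strands, assigns 21-nt
    small RNAs to phase registers and processing cycles anchored at the
    predicted miR173 cleavage site, consolidates sense/antisense duplexes with
    2-nt 3' overhangs, builds miRNA precursor processing profiles, catalogues
    homolog-specific siRNAs, and summarizes transitive spread of secondary
    siRNAs. Includes a synthetic library generator with ground-truth labels so
    every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
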