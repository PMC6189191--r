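Package: lgtscreen
Title: Phylogenomic Screening for Bacterial Gene Transfers into Plastid Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tree-based pipeline for detecting lateral gene transfers (LGT) from
    bacterial donors (notably Chlamydiae) into the nuclear and plastid genomes of
    Archaeplastida. Implements sequence-database dereplication by pairwise identity
    clustering, taxon-capped two-pass homolog sampling from BLAST-style hit tables,
    bootstrap-aware monophyly classification of gene trees with lineage-specific
    interruption rules, non-redundant transfer-event counting via homolog-set
    clustering, congruence-gated alignment concatenation, and monoisotopic adduct
    m/z identification of naphthoquinone metabolites. Ships a synthetic-data
    generator with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
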