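Package: protcurate
Title: Curation of Non-Redundant Protein Sequence Databases and
    Parsimony-Based Protein Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build a non-redundant, annotated protein sequence
    database from a reviewed seed list plus a large unreviewed candidate
    pool, in the style used for manually curated organism-specific
    proteomics databases. Candidate entries are collected by pairwise
    alignment (BLOSUM62, affine gaps) or ingested from BLAST tabular
    output, classified as duplicates, fragments, precursor-only variants
    or genuine sequence variants, and merged into a curated FASTA with an
    annotation table. A companion inference engine performs in-silico
    tryptic digestion, target-decoy q-value filtering of peptide-spectrum
    matches, parsimony (Occam's razor) protein grouping with subset and
    intersection handling, replicate consensus, and comparison of two
    database-search results with per-protein absence explanations.
    Seeded synthetic-data generators provide ground-truth fixtures for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
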