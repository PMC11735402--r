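Package: sgescreen
Title: Design and Analysis of Saturation Genome Editing Variant Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for saturation genome editing (SGE) deep
    mutational scans of a transcript region. Covers exhaustive variant-library
    design (all single-nucleotide variants, minimal-Hamming multi-nucleotide
    codon substitutions, single-base insertions and 1-3 bp deletions, with
    restriction-site silencing), exact-match variant counting from merged
    amplicon reads, enrichment scoring with control-anchored normalization to
    relative fitness scores (RFS), significance testing against a synonymous
    null, detection of nonsense-mediated decay from paired mRNA/DNA counts,
    clinical-classifier calibration (confusion metrics, PR/ROC curves,
    OddsPath evidence strength, Z-prime factors), residue-level structural
    features of protein-DNA complexes, and a seeded synthetic-screen simulator
    for validating every stage without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
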