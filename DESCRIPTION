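Package: nifhcurate
Title: Curation and Analysis of nifH Amplicons and Diazotroph Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for nitrogenase (nifH) functional-gene
    amplicon studies of nitrogen-fixing soil communities. Builds a
    cluster-labelled NifH protein reference database with conserved-motif
    (MgATP-binding and 4Fe-4S ligand) filtering, performs translation-based
    quality control of amplicon sequence variants on the two iron-sulfur
    cluster ligating cysteines (positions 97 and 132 in Azotobacter
    vinelandii numbering), classifies ASVs by protein alignment and
    neighbor-joining tree placement with bootstrap support, summarises
    diazotroph community composition with Shannon diversity and factorial
    ANOVA with Tukey contrasts, and quantifies biologically fixed nitrogen
    from 15N2 microcosm incubations. A synthetic-data generator with known
    ground truth replaces field sequencing and isotope-ratio measurements
    so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    ape,
    vegan,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
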