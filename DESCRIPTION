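Package: mitosre
Title: Strand-Specific Discovery of Mitochondrial RNA Editing and
    Symmetrical RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for discovering RNA
    editing sites in plant mitochondrial genomes from strand-specific
    RNA-Seq. Reads are placed on the mitogenome with an explicit Hamming
    mismatch budget, partitioned into forward and reverse strand groups
    by orientation, and piled up per strand; editing sites are called
    with coverage, frequency and exact binomial significance thresholds,
    filtered for multi-type positions, and screened against high-quality
    DNA variants. Per-strand calls are paired into symmetrical RNA
    editing (SRE) events, annotated for genomic context and codon-level
    consequences of C-to-U edits, and compared across species via
    consensus coordinates of homologous CDS. A synthetic-data generator
    plants editing events, SRE pairs, SNPs and dense editing clusters
    with a written ground truth so that every stage, including the
    calibration of the mapping mismatch budget, is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
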