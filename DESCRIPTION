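Package: caseinsplice
Title: Transcript Isoform Reconstruction and Variant Analysis for Multi-Exon Casein Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and classifying alternatively spliced
    transcript isoforms of multi-exon milk-protein genes from Sanger cDNA clone
    sequences, built around the two donkey alpha-s2-casein paralogs (CSN1S2 I and
    CSN1S2 II). Provides exon-level gene models with cryptic splice-site
    annotations, a declarative splice-event engine, frame-aware conceptual
    translation with signal-peptide cleavage, premature-stop and
    nonsense-mediated-decay flagging and theoretical average molecular weights, a
    dynamic-programming isoform caller for clone libraries, SNV aggregation and
    protein-level annotation, splice-acceptor variant interpretation, in-silico
    restriction digestion and PCR-RFLP genotyping-assay design, and
    Hardy-Weinberg equilibrium statistics, together with seeded synthetic-data
    generators for gene models, clone libraries and genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rtracklayer,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
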