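Package: dpcseq
Title: Genome-Wide Analysis of DNA-Protein Cross-Link Induction and Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of DPC-seq experiments, which map DNA-protein
    cross-links (DPCs) genome-wide from sequencing of KCl-SDS precipitated
    cross-linked DNA. Computes per-gene depth- and length-normalized DPC
    coverage from fragment intervals, metagene and TSS profiles, per-gene
    differential-coverage tests with Bonferroni correction to call genes whose
    DPC repair is transcription-dependent or CSB-dependent, paired Wilcoxon
    signed-rank group tests, stratification of genes by chromatin
    accessibility and RNA polymerase II occupancy with quadrant and
    feature-enrichment summaries, and classification of CRISPRi screen hits
    from DrugZ-format tables. Includes a seeded simulator that generates
    synthetic genomes, formaldehyde-induced DPC landscapes with first-order
    repair kinetics, and sequencing fragments with known per-gene ground
    truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
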