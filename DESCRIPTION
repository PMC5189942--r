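Package: hemisel
Title: Hemizygosity-Stratified Detection of Purifying Selection in Tumor Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects purifying (negative) selection against damaging somatic
    mutations in hemizygously deleted genomic regions of tumors. Classifies
    coding substitutions and indels, assigns trinucleotide (96-class)
    mutational-signature contexts, computes signature-weighted dN/dS with
    one-sided Fisher tests, normalizes phred-like functional-impact scores
    against a signature-based simulated null, and screens genes for lower
    mutation impact in hemizygously deleted versus copy-number-neutral
    samples (one-sided Wilcoxon rank-sum, Benjamini-Hochberg FDR). Includes
    gene-set enrichment, essentiality benchmarking (ROC/AUC), secondary-event
    (homozygous deletion, promoter hypermethylation) analyses, and a
    synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
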