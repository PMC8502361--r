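Package: haplonipt
Title: Proband-Free Noninvasive Prenatal Diagnosis by Linked-Read
    Haplotype Phasing and Relative Haplotype Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Noninvasive prenatal diagnosis of autosomal recessive monogenic
    disorders from maternal plasma cell-free DNA without a proband sample.
    Parental haplotypes are phased directly from barcoded linked-read allele
    observations by greedy 2-coloring of the barcode co-occurrence graph and
    anchored at the pathogenic variant to define pathogenic-linked (P) and
    normal (N) haplotypes. Plasma allele counts at informative SNPs drive a
    two-state hidden Markov model with binomial dosage emissions scaled by the
    fetal fraction and genetic-map (Haldane) transition probabilities; Viterbi
    decoding, rule-based fetal genotype calls, a simulation-based confidence
    score with a no-call threshold, and a complete synthetic-data generator
    for end-to-end validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
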