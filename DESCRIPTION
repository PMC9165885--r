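Package: bgtyper
Title: Blood Group Genotyping from Whole-Genome Sequencing Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts blood-group alleles and diplotypes from per-sample
    whole-genome sequencing variant calls. Computes the baseline cDNA
    differences between a reference genome and the conventional ISBT
    reference allele of each blood-group gene, re-bases sample variants
    onto the conventional alleles, enumerates consistent unphased
    diplotypes against an allele-definition table, and compares cohort
    allele frequencies against external population tables with
    chi-square and Fisher tests. Ships a synthetic-cohort simulator with
    truth tables so the whole pipeline is testable without restricted
    cohort data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
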