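Package: tagwas
Title: Tag-Haplotype Genotype Calling and Nonparametric Association
    Mapping for Multiparental GBS Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genotyping-by-sequencing (GBS) analysis of
    heterozygous, multiparental plant populations: barcode
    demultiplexing and 100 bp tag counting, a ploidy-constrained
    tag-haplotype genotype caller that groups aligned tags by unique
    position and calls unordered haplotype pairs, derivation of
    anther-culture (androgenic capacity) traits, and nonparametric
    genome-wide association mapping using the tie-corrected
    Kruskal-Wallis test with permutation validation and Bonferroni
    corrected Dunn post hoc letters. Includes a simulator of pair-cross
    populations with known founder haplotypes, read depth, sequencing
    error and zero-inflated hurdle traits, so that every stage of the
    pipeline can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
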