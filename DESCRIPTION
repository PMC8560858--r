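Package: arrayscope
Title: Content, Coverage and Imputation Evaluation of SNV Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate and compare SNV genotyping arrays: manifest
    harmonisation and content summaries, inter-array overlap, genome-wide
    coverage from linkage-disequilibrium tagging against a phased reference
    haplotype panel, imputation-quality binning by minor allele frequency,
    per-individual genotype concordance against exome sequencing with
    homozygous-reference masking, GWAS-catalog marker coverage, star-allele
    and HLA identifiability, ACMG proxy-deleterious variant counts,
    mitochondrial locus tallies, and SNV density profiling. A seeded
    synthetic-data module generates block-LD haplotype panels, tag-SNV
    manifests, imputed callsets and truth tables so the whole pipeline is
    testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
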