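Package: xvartest
Title: Variance-Informed Tests of X-Linked Association for Quantitative Traits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Association testing for X-linked quantitative trait loci that
    exploits the phenotypic variance heterogeneity created by X-inactivation.
    In heterozygous females, random silencing of one X copy makes the expressed
    allele a mosaic, inflating trait variance relative to homozygous females.
    The package provides a one-sided Brown-Forsythe-type test of inflated
    heterozygote variance, an inverse-variance weighted regression test of
    association, their Stouffer Z-score combination, and the standard
    ordinary-least-squares test; a simulator of X-inactivation phenotypes with
    a multi-replicate scenario runner for type-I error and power studies; and
    a chromosome-wide scan pipeline for PLINK bed/bim/fam genotypes with
    standard quality control (minor allele frequency, missingness, exact
    Hardy-Weinberg equilibrium in females) and Bonferroni-corrected reporting.
License: MIT
Encoding: UTF-8
Imports:
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
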