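Package: triogxe
Title: Genotypic TDT and Gene-Environment Interaction Tests for Case-Parent Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linkage and association testing in case-parent trios using the
    genotypic transmission disequilibrium test and joint genotype by
    maternal-environment interaction models. For each affected child the three
    Mendelian pseudo-controls are enumerated from the parental genotypes and a
    conditional logistic regression is maximised over the 1:3 matched sets,
    giving per-allele odds ratios, stratum-specific odds ratios for exposed and
    unexposed carriers, Wald and likelihood-ratio tests, and Bonferroni
    correction. Includes PLINK-style .ped/.map trio input, per-marker quality
    control (minor allele frequency, call rate, Mendelian errors, exact
    Hardy-Weinberg test, r-squared de-duplication), a synthetic trio generator
    under Hardy-Weinberg equilibrium with multiplicative ascertainment, and
    simulation-based power estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
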