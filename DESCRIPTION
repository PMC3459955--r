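Package: triopoo
Title: Parent-of-Origin Effects in Case-Parent Trios via Log-Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for parent-of-origin effects (genomic imprinting and
    maternal genotype effects) at biallelic SNPs using case-parent trio
    data. Trios are classified into the 15 Mendelian-compatible (mother,
    father, child) risk-allele dose cells and analysed with a log-linear
    model stratified on parental mating type, with likelihood-ratio tests
    for an imprinting term (alpha) and maternal-effect terms (beta,
    gamma). Includes PLINK-style PED/MAP input, call-rate and Mendelian
    quality control, an ascertained-trio simulator under configurable
    disease-risk models, simulation-based power estimation, and a
    per-SNP report pipeline with Bonferroni correction within analysis
    families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
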