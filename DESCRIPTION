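Package: gdheterosis
Title: Parental Genetic Distance and Heterosis Analysis for Factorial
    Hybrid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-based prediction of hybrid performance in
    plant breeding panels. Computes parental genetic distance from
    multi-allelic SSR band profiles (Nei band-sharing) and biallelic SNP
    genotypes (one minus identity-by-state), handles North Carolina II
    factorial mating designs, derives mid-parent and best-parent
    heterosis from multi-environment phenotypes, clusters parents into
    heterotic groups by UPGMA, and correlates genetic distance with
    hybrid performance within male-parent populations. Includes a
    structured-population simulator (Balding-Nichols SNP frequencies,
    Dirichlet SSR allele frequencies, additive plus dominance trait
    architecture) so every stage of the analysis can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
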