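Package: cwrpop
Title: Population-Genomic Toolkit for Conservation of Crop Wild Relatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed diversity and differentiation statistics (pi, Dxy, Hudson
    Fst, Tajima's D), PLINK-style runs-of-homozygosity scanning, site-pattern
    introgression statistics (Patterson's D with block jackknife, windowed f_d,
    f-branch over a population tree), diagnostic-marker introgression dosage,
    derived deleterious-load accounting with an unfolded site frequency
    spectrum, standardized haplotype divergence, a forward Wright-Fisher
    simulator contrasting selfing and outcrossing under a bottleneck
    demography, and probabilistic bioclimatic niche overlap. A synthetic-cohort
    generator with a known truth channel makes every stage testable without
    external resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
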