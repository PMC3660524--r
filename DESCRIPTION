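Package: tetramap
Title: Linkage Analysis and QTL Mapping in Autotetraploids from SNP Allele Dosage Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic linkage maps and maps quantitative trait loci in an
    autotetraploid F1 (full-sib) population genotyped with SNP allele-intensity
    ratios (theta scores). Provides dosage calling per SNP by normal-mixture
    models fitted with the EM algorithm and selected by BIC; exact two-locus
    gamete and zygote frequencies under random chromosomal segregation with
    bivalent pairing; maximum-likelihood estimation of recombination fractions,
    LOD scores and parental phase for all SNP configuration pairs; linkage-group
    assembly by chi-square independence clustering; weighted least-squares
    ordering with ripple refinement; reconstruction of offspring genotypes along
    the map with a 36-state hidden Markov model; and QTL interval mapping by
    iterative weighted regression on genotype probabilities. A meiosis simulator
    generates populations with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
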