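Package: ralesim
Title: Forward Simulation and Association Testing for Rare Alleles of Large Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of a recombining gene
    region in which recurrent, partially recessive, non-complementing
    deleterious mutations maintain a quantitative disease liability at
    mutation-selection balance.  Haplotype effects are additive over
    causative mutations, the genotypic value of a diploid is the geometric
    mean of its two haplotype effects, and liabilities are under Gaussian
    stabilizing selection.  Includes construction of liability-threshold
    case/control panels, single-marker logistic scans, rare-variant burden
    tests (Madsen-Browning rank sum, Li-Leal Hotelling T2), the
    excess-of-significant-markers (ESM) region statistic with permutation
    based significance, population-genetic summaries (SFS, diversity, LD
    tagging), imperfect-chip marker ascertainment, and a power-evaluation
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
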