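Package: matiMDP
Title: Resource Allocation for Multi-Allelic Trait Introgression via
    Markov Decision Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates marker-based multi-allelic trait introgression (MATI)
    breeding programs and optimises the per-generation progeny allocation with
    a finite-horizon Markov decision process. Provides meiosis simulation over
    binary marker genotypes with independent recombination, exact predicted
    cross value (PCV) computation by dynamic programming with a Monte-Carlo
    oracle, PCV-maximising parental selection with parent retention, empirical
    construction of PCV-interval state spaces and transition matrices from
    preliminary simulations, a backward-induction policy solver with a
    brute-force enumeration oracle, and an experiment suite covering
    cost/time/probability trade-offs, static versus dynamic allocation
    comparisons, optimal total budget estimation by nonlinear revenue
    regression, and per-generation budget breakdowns.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
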