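Package: marates
Title: Mutation-Rate Estimation and Power Analysis for Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of mutation-accumulation (MA) experiments
    from curated per-line mutation tables: per-site per-division mutation
    rates with exact (Garwood) Poisson confidence intervals, six-class
    conditional base-substitution spectra with per-line standard errors,
    transition/transversion and A/T-direction bias statistics, two-group
    Poisson rate-ratio tests (Wald and exact conditional binomial),
    Yates-corrected chi-square tests for selection on coding mutations,
    codon-degeneracy synonymous/nonsynonymous site counting, harmonic-mean
    effective population size for single-cell-bottleneck serial-transfer
    lines, and a Monte-Carlo power analysis for two-group rate comparisons.
    Includes a synthetic MA-experiment generator so every analysis stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
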