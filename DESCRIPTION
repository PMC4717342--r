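Package: strainseg
Title: Segregation and Co-Transmission of Heritable Symbiont Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the vertical transmission of two co-infecting strains of a
    maternally transmitted symbiont (the filamentous virus LbFV of the
    Drosophila parasitoid Leptopilina boulardi) under the hypothesis that each
    strain is transmitted independently of the other. Provides the four-state
    Markov chain over infection statuses (uninfected, strain 1, strain 2,
    coinfected), stochastic simulation of isofemale lines, a Monte-Carlo null
    distribution for the number of coinfected lines with an empirical two-sided
    p-value, exact binomial tests of co-transmission against the independence
    product, Clopper-Pearson rate estimates, protection ratios for horizontal
    transfer, PCR deletion-marker genotype calling, and synthetic-data
    generators emulating the vertical, segregation and horizontal-transfer
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
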