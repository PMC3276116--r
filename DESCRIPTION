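Package: lineorigin
Title: Line-Origin Probabilities in Outbred Line Crosses via Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates, for every F2 individual of a cross between two outbred
    lines, the posterior probability at each genomic test position that its
    maternal and paternal haplotypes descend from line 1 or line 2, using a
    scaled forward-backward algorithm over a four-state hidden Markov model
    with Haldane map-distance transitions and Mendelian-compatibility
    emissions. Includes a three-generation intercross simulator (gamete
    dropping with Poisson crossover counts and uniform positions), a parental
    phasing procedure, and evaluation statistics for inferred recombination
    switches (line-origin error, imprecision, inaccuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
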