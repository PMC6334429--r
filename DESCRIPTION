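Package: gspr
Title: Gene Selection Programming for High-Dimensional Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for samples-by-genes expression matrices
    using Gene Selection Programming, a Gene Expression Programming variant in
    which fixed-length Karva chromosomes encode candidate gene subsets. The
    population initializer draws terminals by roulette-wheel selection over
    Information-Gain weights, fitness combines leave-one-out cross-validated
    linear-SVM accuracy with a subset-size parsimony term, and mutation and
    recombination are guided by attribute weights with accept-if-better rules.
    Includes a synthetic microarray-like data generator with known informative
    genes, broom-style tidiers, ggplot2 plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
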