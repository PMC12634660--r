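Package: soseq
Title: Context Modulation Analysis of Behavioral Syllable Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of frame-wise behavioral syllable sequences
    from solitary and dyadic (social) open-field recordings of mice. Provides
    bout and syntax extraction, onset/frame proportion tables and
    context-modulation testing (Mann-Whitney U with Benjamini-Hochberg
    correction), bout-transition networks with eigenvector centrality and
    per-edge modulation tests, contact-aligned Kullback-Leibler divergence
    time-courses with randomized controls, Hamming-distance syntax families
    and rolling-window occupancy against inter-mouse distance change,
    parametric social-behavior classes in (distance, change-in-distance)
    space, and PCA-based context discrimination. Includes a fully seeded
    synthetic-experiment generator with planted, recoverable effects for
    validation, plus readers and writers for the plain-text artifact formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    MASS,
    cluster,
    igraph,
    ape,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
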