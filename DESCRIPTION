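Package: otomir
Title: MicroRNA Association Analysis for Hearing Dysfunction Under
    Combined Solvent and Noise Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking circulating microRNA
    expression to auditory function (pure-tone hearing level and
    distortion-product otoacoustic emission band levels) in workers
    co-exposed to ototoxic solvents and noise.  Provides a synthetic
    cohort generator with planted ground truth, high-resolution DPOAE
    spectrum processing (coherent averaging, zero-latency component
    unmixing, third-octave band levels), negative-binomial differential
    expression with TMM normalization, correlation-based microRNA
    screening, mixed-effects band-wise association models, sparse PLS
    discriminant analysis, and an auto contractive map neural network
    with minimum spanning tree projection and Spin Net equilibrium
    queries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
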