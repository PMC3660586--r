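Package: segqtl
Title: Major-Gene plus Polygene Segregation Analysis and QTL Mapping for
    Biparental Plant Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint segregation analysis of quantitative traits in the six
    classical generations of a biparental plant cross (P1, P2, F1, BC1,
    BC2, F2) under a catalogue of 24 major-gene plus polygene mixed
    inheritance models, fitted as constrained normal mixtures by an
    iterated expectation-conditional-maximisation (IECM) algorithm with
    AIC model selection and a uniformity-based goodness-of-fit battery;
    first- and second-order genetic parameter estimation (additive,
    dominance and epistatic effects, major-gene and polygene
    heritabilities); composite interval mapping of QTL in F2/F3 designs
    with stepwise cofactor selection and permutation thresholds;
    linkage-map summary statistics and segregation-distortion tests; and
    seeded simulators for six-generation phenotypes and marker-QTL cross
    data.
License: MIT
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
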