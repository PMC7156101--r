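Package: coopscape
Title: Public-Goods Cooperation in Resource-Heterogeneous Metapopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and simulation tools for studying the evolution of
    public-goods cooperation (siderophore production) in metapopulations with
    heterogeneous resource availability. Provides closed-form and numeric
    evolutionarily stable strategy (ESS) analysis under hard and soft
    selection, a serial-transfer metapopulation simulator mirroring
    paired-microcosm experimental-evolution designs, assay read-out
    computations (Malthusian relative fitness, per-capita chrome azurol S
    iron-chelator activity) with the routine comparison statistics, and a
    synthetic-data generator with known ground truth for exercising the full
    pipeline.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
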