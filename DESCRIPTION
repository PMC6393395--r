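Package: hairpintools
Title: Force Spectroscopy and Secondary-Structure Analysis of DNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for single-molecule analysis of DNA hairpin folding,
    built around integron attC recombination sites. Provides worm-like-chain
    (WLC) polymer elasticity models and their serial combination for
    handles-plus-hairpin optical-tweezers constructs; detection of unfolding
    and refolding events in force-extension traces with WLC segment fitting
    and contour-length-change extraction; Gaussian-mixture analysis of
    bimodal contour-length-change populations; a DNA nearest-neighbor
    secondary-structure folding engine with banded suboptimal enumeration;
    classification of hairpin conformers (straight versus kinked, complete
    versus incomplete) from attC box annotations with Boltzmann ensemble
    occupancies; a batch site-screening pipeline; and simulators that
    generate realistic force-extension traces and attC-like sequence
    fixtures for end-to-end validation.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
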