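Package: mammetamer
Title: Deep Texture Synthesis and Psychophysical Evaluation of Mammogram-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating texture metamers of mammogram-like images and
    for evaluating them psychophysically. Provides a seeded generator of
    mammogram-like phantoms in four diagnostic classes, a small configurable
    convolutional feature hierarchy with deterministic weights, Gram-matrix
    texture statistics with an exact pixel-level gradient and projected
    gradient-descent synthesis from white noise, ROI- and saliency-centered
    partial-view patch extraction with explicit skip rules, and a simulation
    and analysis suite for signal-detection (d-prime) and representational
    similarity (RDM, congruity, hierarchical clustering) experiments with
    simulated observers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
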