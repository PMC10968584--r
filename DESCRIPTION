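Package: problgmd
Title: Probabilistic LGMD Collision-Perception Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a probabilistic variant of the lobula giant movement
    detector (LGMD) neural network for visual collision perception, in which
    signal transmission between the photoreceptor, excitatory, inhibitory and
    summation layers and the output cell is gated by independent Bernoulli
    random variables sharing one probability parameter. Includes the
    deterministic classic-LGMD limit, a synthetic looming-stimulus generator,
    salt-and-pepper and Gaussian noise models (on inputs and on intermediate
    layers), median/Gaussian pre-filter baselines, the distinct-ratio
    peak-versus-background statistic, replicate-trial aggregation and
    probability-parameter sweeps, plus a small command-line driver for
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    tiff
Config/testthat/edition: 3
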