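Package: clonemorph
Title: Morphological and Network Phenotyping of Clonal Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies single-cell morphology and cell adjacency network
    topology from instance-segmented 2D microscopy label images, fits
    density-dependent morphological progressions for clonal lineages,
    clusters clones into morphological subclasses, quantifies 3D spheroid
    invasion (protrusions and disseminated cells) from confocal z-stacks,
    and relates 2D and 3D phenotypes through Spearman correlation graphs
    and a composite invasion score. Includes a synthetic-data generator
    that plants cells, progressions and spheroids with analytic ground
    truth so that every stage is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    graphics,
    igraph,
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
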