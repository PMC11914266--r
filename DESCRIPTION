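Package: venncf
Title: Area-Based Colocalization Factors for Multichannel Superresolution Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies colocalization among fluorescently labelled proteins
    that form 100-nm-scale cytoplasmic microdroplets, from multichannel
    superresolution micrographs. Each channel is binarized, the binary masks
    are partitioned into exact Venn regions, and every region's observed area
    fraction is compared with its expectation under a random-placement
    independence null to give a Colocalization Factor (CF); CF = 1 means no
    association. Across replicate cells the package summarises CFs, runs a
    one-way ANOVA with pairwise comparisons against a reference region, and
    infers which of three proteins scaffolds the other two from the ordering
    of exclusive-pair CFs. A synthetic droplet-image simulator with a
    controllable scaffold channel and an exact independence null supports
    calibration and power studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
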