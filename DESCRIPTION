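Package: visrep
Title: Ecologically Guided Dataset Curation and Representational
    Similarity Statistics for Visual System Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating image datasets and deep
    network models of the human ventral visual stream. Covers lexical
    category selection by a frequency-concreteness index, PCA-based
    near-duplicate image detection, size-matched dataset trimming,
    correlation-distance representational dissimilarity matrices (RDMs),
    noise ceilings, permutation and bootstrap inference over network
    instances, stimulus-wise animacy analyses, percentage-bend robust
    correlation, in-silico mapping of face-selective units, and effective
    receptive-field arithmetic for convolutional layer stacks. Includes
    seeded synthetic-data generators emulating the statistical structure
    of each input so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
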