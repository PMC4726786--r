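Package: neurospan
Title: Time-Aligned Brain-Behavior HDF5 Files and Unsupervised Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, write and validate a schema-based HDF5 format for
    time-aligned multichannel neurophysiology (ECoG/EEG) and behavioral
    annotation data, extract multi-timescale high-gamma (60-100 Hz)
    band-power features, index all-pairs Pearson similarity between time
    windows as a sparse significance-span index, answer timescale-resolving
    interval queries, and validate retrieval quality with label-based ROC
    analysis. Includes a deterministic synthetic ECoG generator with block
    task structure for end-to-end testing.
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
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
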