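Package: tslod
Title: Level-of-Detail Storage and Constant-Complexity Queries for Huge Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Out-of-core storage and viewport-query engine for very long
    single-channel recordings (e.g. extracellular electrophysiology) and their
    annotations. Builds static min/max data-reduction pyramids over flat binary
    sample files, stores editable event and interval annotations in sparse
    bit-trie directory trees with reduced proxy node files, and answers
    pan/zoom viewport queries in constant time by combining static level
    selection with dynamic reduction. Includes the synthetic benchmark
    fixtures (alternating series, dense events, stipple intervals, spike
    trains), storage-overhead accounting, a read-cost sweep harness, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
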