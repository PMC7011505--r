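Package: kd2d
Title: Two-Dimensional Krawtchouk Descriptors for Local Image Search
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Content-based local image retrieval with two-dimensional
    Krawtchouk descriptors (2DKD). Weighted Krawtchouk moments of a
    window around a point-of-interest are reduced to six translation-,
    rotation- and scale-invariant components, which are indexed for
    every subimage of an image database and ranked by squared Euclidean
    distance at query time. Includes a synthetic icon benchmark with
    rotation, scaling, random placement and salt-and-pepper degradation
    for measuring retrieval accuracy, and a command-line interface for
    describing, indexing, searching and benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
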