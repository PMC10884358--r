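Package: metamicrostates
Title: Cross-Study Comparison and Meta-Clustering of EEG Microstate
    Template Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare resting-state EEG microstate template maps
    across studies with heterogeneous electrode montages.  Provides
    polarity-invariant topographic similarity (shared variance between
    average-referenced, unit-norm scalp maps), spherical-spline
    interpolation between electrode montages, classical multidimensional
    scaling of global map dissimilarities, subject-weighted modified
    k-means meta-clustering of template maps, backfitting of meta-maps to
    study template maps and to continuous EEG, commonality-of-assignment
    matrices across cluster numbers, and a findings database queryable by
    topographic similarity rather than by class label.  Includes seeded
    generators for synthetic montages, prototype topographies,
    multi-study atlases and microstate-structured EEG, plus a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
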