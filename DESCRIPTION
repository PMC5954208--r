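Package: varietywalk
Title: Variety Metrics for Free-Play Walking Paths and Walk-Training Courses
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the variety of 2D walking paths recorded as
    timestamped foot placements in a bounded playroom: segments step
    streams into walking bouts, computes per-bout path curvature
    (straightness index), turning-angle statistics, and a four-dimensional
    variety profile (shape, direction, length variety, and number of
    bouts) per walker.  Partitions walkers into equal-size groups with a
    balanced (equal-cardinality) k-means whose assignment step solves an
    exact transportation problem.  Builds walk-training courses for
    humanoid-robot gait optimization, both from recorded paths (capped
    stops, randomly sampled fixed-duration blocks, concatenation) and
    from geometric baselines (line, circle, square).  Scores round-robin
    tournaments of head-to-head matches into league tables, win and goal
    matrices, and goal-difference statistics.  A correlated-random-walk
    generator produces synthetic free-play sessions with controllable
    variety structure so the full pipeline is testable without video
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
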