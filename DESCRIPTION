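Package: cowreid
Title: Orientation- and Behaviour-Conditioned Re-Identification of Holstein-Friesian Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embedding-based re-identification of Holstein-Friesian cattle from
    instance segments under variable pose. Provides a procedural generator of
    pied-coat instance segments with independent left/right flank textures, a
    lightweight inception-style embedding network (32-dimensional L2-normalised
    descriptors) trained with histogram loss under behaviour- and
    orientation-conditional batch sampling, a metadata-aware reference-gallery
    search with k-nearest-neighbour identity voting and joint unique-assignment,
    the multi-task keypoint/behaviour loss with adaptive term balancing,
    skeleton-based orientation estimation, and rank-n (CMC) evaluation with
    exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
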