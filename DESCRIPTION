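Package: emorsa
Title: Searchlight Representational Similarity Analysis of Emotion
    Concept Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links idiosyncratic conceptual knowledge of emotion
    categories to neural representational geometry. Builds per-subject
    conceptual dissimilarity matrices (Pearson correlation distance) from
    emotion-word rating tables, embeds them with Kruskal nonmetric
    multidimensional scaling and Ward hierarchical clustering, relates
    conceptual dissimilarity to emotion-categorization confusions,
    estimates single-trial response amplitudes with a Least Squares
    Separate general linear model, runs searchlight representational
    similarity regression of neural on conceptual (and low-level control)
    dissimilarities, and performs group inference with one-sample
    sign-permutation tests under threshold-free cluster enhancement.
    Includes a seeded synthetic-data generator that plants known
    representational structure in behavioral ratings, confusion counts,
    and beta volumes so every stage of the pipeline is testable end to
    end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
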