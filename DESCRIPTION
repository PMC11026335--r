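Package: feedbackRSA
Title: Decoding and Representational Analysis of Cortical Feedback Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for decomposing feedback signals in non-stimulated
    (occluded) visual-cortex voxels into contextual and mnemonic components.
    Implements the full analysis chain of an fMRI occlusion paradigm:
    experimental-design generation and a generative simulator for subject and
    cohort voxel patterns with known signal content, least-squares-separate
    single-trial beta estimation from simulated BOLD runs, contextual and
    mnemonic cross-classification decoding with leave-one-run-out
    cross-validation and a two-step permutation/bootstrap group test,
    cross-validated Mahalanobis (crossnobis) and Pearson-distance
    representational dissimilarity matrices with binary model-RDM rank
    correlation, and differentiation-index statistics with outlier screening,
    rank correlation of feedforward against feedback differentiation, and
    Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
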