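Package: gradalign
Title: Orthogonal Procrustes Alignment of Functional Connectivity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the number of components used in orthogonal
    Procrustes alignment affects the aligned principal functional-connectivity
    gradient. Provides spectral gradient extraction from parcellated BOLD time
    series (row sparsification, five affinity kernels, diffusion map embedding,
    PCA and Laplacian eigenmaps), pairwise Procrustes alignment to a holdout
    group reference with correspondence, transformation-magnitude and
    principal-angle diagnostics, connectome fingerprinting (identification
    accuracy and differential identifiability), head-motion metrics (framewise
    displacement, typicality of functional connectivity) and their correlation
    sweeps with FDR correction, confound-aware nested cross-validated
    prediction, and a deterministic multi-session synthetic cohort generator
    so the full pipeline can be exercised without access to restricted fMRI
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    e1071,
    ranger,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
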