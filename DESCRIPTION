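Package: hydracluster
Title: Semi-Supervised Max-Margin Subtyping of Case-Control Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transdiagnostic subtyping of clinical cohorts from ROI-level cortical
    morphometry (cortical thickness or surface area). Implements HYDRA-style
    semi-supervised discriminative clustering, in which k subtypes are sought
    within the clinical group while each subtype is separated from controls by
    its own regularized max-margin hyperplane (the hyperplanes forming a convex
    polytope), with nuisance-covariate adjustment and consensus over random
    restarts. Cluster number is selected by cross-validated adjusted Rand index
    with a permutation null; downstream characterization covers FDR-corrected
    case-control comparisons, chi-square diagnosis-by-subtype tables, one-way
    ANOVA with Tukey post-hoc, conjunction masks with resting-state-network
    summaries, and dice membership consistency across atlases and inclusion
    criteria. A synthetic cohort generator with planted subtype structure makes
    the whole pipeline testable without access to raw MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
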