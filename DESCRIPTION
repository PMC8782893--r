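Package: neurocrosslag
Title: Longitudinal Brain-Behavior Analysis with Eigenvector Centrality
    Mapping and Voxelwise Cross-Lagged Panel Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reciprocal longitudinal relationships between
    resting-state functional connectivity and behavioral symptom counts over
    two timepoints. Functional connectivity is summarized per voxel by
    eigenvector centrality, computed matrix-free from a rectified (entirely
    nonnegative) correlation matrix by power iteration, then rank-based
    inverse-normal transformed and residualized for head motion. Voxelwise
    autoregressive cross-lagged path models relate baseline centrality to
    follow-up symptoms (and vice versa) while adjusting for covariates;
    suprathreshold clusters receive familywise-error corrected p-values from
    Gaussian random field theory. Robustness utilities cover family-member
    selection, symptom-count diagnosis, Wilcoxon signed-rank change tests,
    zero-inflated Poisson regression, and interscan-interval trimming. A
    synthetic-data module generates cohorts and 4D volumes with known latent
    connectivity structure and a planted cross-lag effect, so the entire
    pipeline can be validated against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
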