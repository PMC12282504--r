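Package: bbpls
Title: Behavioral Partial Least Squares for Brain-Behavior Mapping
Version: 0.1.0
Authors@R: person("bbpls", "maintainers", email = "bbpls@example.org", role = c("aut", "cre"))
Description: Partial least squares correlation (behavioral PLS) linking a
    brain-imaging block (e.g. restricted-diffusion values across white-matter
    tracts and subcortical regions) to a multi-domain behavioral block in the
    same subjects. Implements age residualization and column z-scoring, singular
    value decomposition of the cross-block correlation matrix into latent
    variables, permutation tests of singular values with Procrustes alignment,
    bootstrap ratios and loading confidence intervals, repeated train/test
    split validation of projected scores, effective-rank estimation from the
    eigenvalue spectrum, and downstream clinical applications (diagnostic
    subtype contrasts, prospective partial correlations with follow-up symptom
    severity, and cohort descriptive tables). Includes a synthetic-cohort
    generator with a planted low-rank cross-block covariance for calibration
    and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
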