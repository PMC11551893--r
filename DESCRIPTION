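Package: seqmvpa
Title: Multivariate Pattern Analysis of Movement-Sequence Preparation and
    Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multivariate analysis of condition-by-run fMRI
    activation patterns from motor sequence experiments. Implements
    factorized linear discriminant decoding of sequence order, timing and
    their non-additive integration with run-wise cross-validation and
    binomial z-normalization of accuracies; shrinkage-regularized noise
    covariance estimation and prewhitening; cross-validated Mahalanobis
    (crossnobis) representational dissimilarity matrices; classical
    multidimensional scaling with a normalized cross-phase distance
    statistic and simulation-matched no-switch baselines; ROI-constrained
    volumetric searchlight mapping with group-level random-effects t-maps;
    and a generative simulator of condition-by-run voxel patterns with
    controllable spatial, temporal, integrated, run and noise components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
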