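Package: radirep
Title: Reproducibility Screening of MR Radiomics Features Across Scanners
    and Acquisition Parameters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the robustness of T2-weighted MR radiomics
    features across scanners and acquisition parameters. Implements a
    396-feature catalog (histogram, form factor, GLCM, run-length, size-zone,
    cluster and correlation families), decile piecewise-linear intensity
    normalization against a reference landmark map, histogram-equalization
    gray-level discretization, coefficient-of-variation and quartile
    coefficient-of-dispersion reproducibility screening, hierarchical-cluster
    selection of representative robust features, and ROC evaluation of their
    tissue-discrimination power. A synthetic multi-scanner phantom generator
    (textured single-tissue and two-layer designs, monotone inter-scanner
    intensity transforms, acquisition-parameter sweeps) provides ground-truth
    study designs for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    pROC,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
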