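Package: qusrad
Title: Quantitative Ultrasound Radiomics for Breast Cancer Recurrence-Risk
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for predicting Oncotype DX recurrence-risk
    category from quantitative ultrasound (QUS) spectral parametric images.
    Implements radiofrequency (RF) phantom simulation with known scattering
    ground truth, spectral parametric mapping (mid-band fit, spectral slope,
    spectral intercept, average scatterer diameter, average acoustic
    concentration) via sliding-window spectrum estimation, attenuation
    correction and Gaussian form-factor inversion of the backscatter
    coefficient, IBSI-style two-dimensional radiomics feature extraction
    (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM, GLDM over original and
    Coif1 wavelet subbands), and a nested leave-one-out cross-validated
    classification protocol with MRMR filtering, SMOTE or class-weight
    imbalance handling, sequential forward selection, grid search, and a full
    confusion-matrix metric panel, plus univariate feature screening with
    Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    class,
    e1071,
    randomForest,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
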