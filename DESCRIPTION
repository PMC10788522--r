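Package: BrainHeart
Title: Brain-Heart Coupling After Stroke: HRV Metrics, Lesion-Covariate
    Fusion and Time-Resolved Directed Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the interplay between stroke lesions and
    cardiac autonomic regulation. Implements resting heart rate variability
    (HRV) analysis of R-R interval series (time-domain metrics, FFT band
    powers, cohort-referenced z-scoring), parallel ICA fusion of lesion maps
    with HRV covariates, atlas-based lesion-pattern quantification,
    seed-to-network directed connectivity by time-resolved partial directed
    coherence (dual extended Kalman filter over time-varying MVAR models)
    with surrogate-data significance testing (window-shuffle bootstrap, time
    reversal, AAFT), and support-vector-regression validation of
    connectivity values. Ships a synthetic-data module that generates every
    input class with known ground truth so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    RNifti,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'hrv.R'
    'io.R'
    'lesion-mapping.R'
    'parallel-ica.R'
    'pipeline.R'
    'surrogates.R'
    'svr-validation.R'
    'synthetic-data.R'
    'tpdc.R'
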