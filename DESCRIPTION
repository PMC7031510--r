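Package: hvcx
Title: Conductance-Based Modelling and Population Statistics of HVC_X Intrinsic Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley-type modelling of basal-ganglia
    projecting (HVC_X) neurons of the songbird premotor nucleus HVC. Simulates
    current-clamp step protocols, extracts spike waveform and spike train
    features from voltage traces, fits five maximal ionic conductances (Na, K,
    SK, h, Ca-T) to paired depolarizing/hyperpolarizing responses by exhaustive
    grid search with a multi-feature error function, and quantifies population
    structure of the fitted conductances: within-bird homogeneity, between-bird
    heterogeneity, hyperellipsoid (trace and geometric) volumes, Mahalanobis
    distances, MANOVA with Wilks' lambda, bespoke spike-timing and waveform
    variance tests, and the correlation between song similarity and
    conductance-space distance. A seeded synthetic-cohort generator emulates
    adult, juvenile and delayed-auditory-feedback populations so the whole
    pipeline runs and is validated without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'hh-parameters.R'
    'hh-simulate.R'
    'trace-features.R'
    'fitting.R'
    'hvcx-package.R'
    'io.R'
    'population-stats.R'
    'synthetic-cohort.R'
    'pipeline.R'
    'population-tests.R'
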