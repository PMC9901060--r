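Package: graphDBP
Title: Graph Representation Learning for Forecasting Diastolic Blood
    Pressure from Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds per-patient temporal knowledge graphs from
    longitudinal electronic health record (EHR) events and forecasts the
    diastolic blood pressure (DBP) of a heart-failure patient's future
    visit with a Graph Transformer: masked scaled dot-product
    self-attention gated by a cohort-wide event co-occurrence matrix,
    composed with a graph convolution over the temporal adjacency, a sum
    readout and a linear head.  Includes readers and writers for
    long-table and record-per-line cohort files, ICD-based heart-failure
    cohort filters, drug-category assignment, tf-idf comorbidity
    weighting, a synthetic EHR cohort simulator with a known generative
    DBP process, 10-fold cross-validation with MAE/MSE/RMSE reporting,
    multi-step evaluation, medication and subtype stratification, an MLP
    baseline, and patient-embedding export with silhouette scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    cluster,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
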