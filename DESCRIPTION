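Package: hclpheno
Title: Immunophenotypic Classification of Hairy Cell Leukemia and HCL-like Disorders
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for immunophenotypic classification of hairy cell leukemia
    (HCL) against HCL-like disorders (HCL variant / splenic diffuse red pulp
    lymphoma and HCL-like NOS) from flow-cytometry data. Summarizes
    event-level fluorescence into per-sample marker profiles (percent
    positive, median fluorescence intensity, intensity class), computes the
    4-marker (CD11c/CD25/CD103/CD123) and CD26-extended 5-marker immunologic
    HCL scores with evaluable-denominator diagnostic evaluation, performs
    PCA-based unsupervised reclassification with 90% concentration ellipses
    and gray-zone flagging, and compares survival endpoints (TTNT, PFS, OS)
    with a product-limit estimator and log-rank test. Includes a calibrated
    synthetic cohort generator and a deterministic 82-patient fixture cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
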