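Package: vestisom
Title: Multi-Layer Self-Organizing Map Phenotyping of Balance and
    Vestibular Test Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised phenotyping of concussion patients from wide
    balance/vestibular diagnostic batteries. Provides a synthetic cohort
    generator with the 8-block, 53-variable schema of a clinical
    balance/vestibular test battery; sentinel-aware ingestion with median
    imputation and z-scoring; cluster-count selection by repeated internal
    validity criteria (Calinski-Harabasz, silhouette, gap, Davies-Bouldin)
    with a mode-with-majority vote; a batch self-organizing map on a
    hexagonal sheet lattice with Epanechnikov neighbourhood, two-phase
    training, quantization/topographic errors and U-matrix; a stacked
    multi-layer SOM with mode-of-repetitions consensus and a three-repetition
    stability protocol; leave-one-test-out and gated leave-one-variable-out
    feature importance; and nonparametric group comparison (Mann-Whitney U
    with tie-corrected normal approximation and exact small-sample path,
    eta-squared effect sizes, Bonferroni correction, chi-squared/Fisher
    symptom contrasts) plus varimax-rotated principal component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
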