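Package: qhtscreen
Title: Quantitative HTS Assay-Interference Analysis and Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Concentration-response processing and hit calling for
    quantitative high-throughput screens of luciferase-inhibition and
    autofluorescence assay interference: plate normalization and pattern
    correction, Hill-equation fitting with signed curve classification,
    multi-filter active-chemical identification with cross-endpoint overlap
    analysis, structure curation and 2D molecular descriptor computation
    with correlation-based selection, chemical-space analysis by
    self-organizing maps, Ward clustering and PCA, and an
    ensemble-undersampled QSAR system scored by Matthews correlation that
    predicts per-endpoint interference probability for new structures.
    Includes a synthetic-data generator with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    minpack.lm,
    randomForest,
    e1071,
    rpart,
    nnet,
    MASS,
    class,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
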