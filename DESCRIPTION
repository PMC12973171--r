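Package: fragwave
Title: Cancer Detection from Cell-Free DNA Fragment-Size Profiles with
    Wavelet Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Classifies patients as cancer or healthy from cell-free DNA
    (cfDNA) fragment-size distribution profiles derived from paired-end
    whole-genome sequencing. Fragments are aggregated into 1-Mb genomic
    bins, augmented by disjoint bin subsampling into multiple
    probability-mass-function profiles per patient, transformed with a
    discrete wavelet transform, and classified with logistic regression,
    random forest, or a small feed-forward neural network. Patient status
    is called by consensus or majority vote over subsample predictions,
    and performance is assessed over patient-grouped stratified train-test
    splits and cross-validation. A synthetic cohort generator emulating
    the mono-nucleosomal 166-bp mode, the 10-bp sub-150-bp periodicity,
    and a tumor-fraction-dependent excess of short fragments makes the
    full pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    randomForest,
    Rsamtools,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
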