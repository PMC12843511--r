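Package: orgfate
Title: Organoid Time-Lapse Morphometrics and Tissue-Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for 96-well brightfield time-lapse imaging of
    single organoids: a seeded synthetic acquisition generator with ground
    truth, classical organoid segmentation with the resize/binarize/QC rules
    used for large-scale screens, a fixed 165-feature morphometrics
    extractor, pigment-area quantification by Yen global plus Sauvola local
    thresholding with percentile size-class binning, PC-space heterogeneity
    and embedding-fidelity diagnostics, leave-one-experiment-out outcome
    prediction with calibrated, ensembled classifiers evaluated by
    per-timepoint weighted F1 curves and paired Wilcoxon comparisons, and
    consensus metrics for saliency-map agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    nnet,
    MASS,
    ranger,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
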