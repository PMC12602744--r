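Package: vocalmarkers
Title: Vocal Biomarker Extraction and Explainable Classification for Neurological Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening neurological disease from voice recordings of
    sustained vowels and short speech items. Implements a synthetic glottal
    pulse-train generator with controllable jitter, shimmer, harmonic-to-noise
    ratio and formant structure; extraction of 28 vocal biomarkers across the
    acoustic (fundamental frequency, formants, jitter, shimmer, HNR),
    articulation (vowel space areas, formant centralization ratio) and cepstral
    (MFCC, cepstral peak prominence, zero-crossing rate, spectral centroid)
    domains; a dataset pipeline with standardization, mean imputation,
    augmentation and stratified splitting; five classifier families with
    confusion-matrix metrics and cross-validated ROC/AUC; and exact and sampled
    Shapley-value attribution for model explainability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    xgboost,
    randomForest,
    rpart,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
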