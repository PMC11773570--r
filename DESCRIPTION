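Package: ramancs
Title: Compressive Sensing Evaluation for Raman Hyperspectral Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Evaluates how far Raman hyperspectral measurements can be
    randomly under-sampled in the spectral domain before downstream
    chemistry breaks. Provides seeded synthetic generators for low-rank
    Raman scenes (two-component hydration mixtures, a cell scene with a
    rare drug component, a layered tissue scene with a large fluorescence
    background), random observation masks, nuclear-norm matrix completion
    solved with FISTA and singular value thresholding, a standard Raman
    preprocessing chain (iterative polynomial baseline removal, median
    despiking, Savitzky-Golay smoothing, max normalization), partial
    least-squares concentration regression with leave-one-concentration-out
    validation and a coefficient-of-variation limit of quantification,
    k-means segmentation with peak-based rare-component detection, and
    PCA-based tissue clustering, plus orchestrated sparsity sweeps that
    emit tidy, machine-readable reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
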