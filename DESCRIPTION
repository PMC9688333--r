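Package: serschemo
Title: Chemometric Classification of Label-Free SERS Biofluid Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for diagnosing disease state from label-free
    surface-enhanced Raman spectroscopy (SERS) of biofluids: spectral
    preprocessing (asymmetric least squares baseline removal,
    Savitzky-Golay smoothing, despiking, fingerprint cropping, mean
    normalization), partial least squares discriminant analysis (PLS-DA)
    with variable importance in projection (VIP) band selection,
    subject-stratified k-fold cross-validation with fold-averaged ROC
    curves, and a synthetic SERS dataset generator for end-to-end
    verification when patient spectra are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
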