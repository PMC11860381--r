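Package: ryegrassNIR
Title: PLS-DA Classification of Perennial Ryegrass Seed Cultivar and
    Endophyte Status from NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for classifying perennial ryegrass
    (Lolium perenne) seed lots by cultivar and Epichloe endophyte status
    (E+/E-) from Fourier-transform near-infrared absorbance spectra.
    Provides a uniform-wavenumber-grid spectra container with CSV and
    JCAMP-DX readers, the standard spectral pre-treatments (detrend,
    SNV, MSC, EMSC, Savitzky-Golay derivatives, mean centering) as
    composable calibration-fitted pipelines, Kennard-Stone sample
    selection, venetian-blinds cross-validation, Q-residual outlier
    screening, binary PLS-DA via NIPALS with nested class-elimination
    sequences, hierarchical decision trees of binary models with an
    "otherwise" fail branch, bag-level majority voting over replicated
    sub-sample scans, and a synthetic spectra generator reproducing the
    reference seed-bag design for fully testable end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
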