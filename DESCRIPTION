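Package: specmargin
Title: Vibrational Spectroscopy Discrimination of Tumor and Margin Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating tumor from healthy-margin tissue in
    FT-IR and Raman hyperspectral maps. Implements the full chemometric
    chain: low-SNR spectrum rejection, Savitzky-Golay smoothing, rubberband
    (lower convex hull) baseline correction, cosmic-ray despiking, area
    normalization, per-spectrum ester-band (1746 1/cm) integral scoring with
    lipid-rich spectrum filtering, and PC1-score classification with ROC/AUC
    and loading-feature band assignment. Ships a calibrated synthetic tissue
    spectrum generator emulating a homogeneous low-lipid tumor class and a
    heterogeneous margin class with lipid-rich domains, for testing and
    method study when real tissue maps are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    e1071,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
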