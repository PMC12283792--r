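Package: ecogflex
Title: Decoding Continuous Finger Flexion from ECoG Wavelet Spectrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding continuous finger-flexion trajectories from
    multichannel electrocorticography (ECoG). Raw 1 kHz recordings are
    normalized, band-pass and notch filtered, transformed into 3D
    (channel x frequency x time) Morlet wavelet amplitude spectrograms at
    100 Hz, segmented into overlapping sliding windows, and decoded into
    five finger trajectories by a 1-D dilated-convolution encoder /
    transposed-convolution decoder trained with a combined mean-squared-error
    and cosine-similarity loss. Includes a loader for BCI Competition IV
    dataset 4 MATLAB files, an HDF5 container for derived artifacts, a
    synthetic ECoG generator with known band-power-to-trajectory coupling
    for end-to-end validation, Pearson-correlation evaluation, and an
    ablation harness over wavelet family, dilation, upsampling mode and
    window stride.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    signal,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
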