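Package: vmdrbf
Title: Hybrid One-Step ECG Forecasting via Variational Mode Decomposition,
    Phase-Space Reconstruction and RBF Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes a single-channel physiological time series (ECG) into
    band-limited intrinsic mode functions by variational mode decomposition
    (spectral ADMM), reconstructs each mode's phase space by delay embedding
    with mutual-information delay selection and false-nearest-neighbour
    dimension selection, trains one exact-interpolation Gaussian radial basis
    function network per mode, and sums the per-mode one-step-ahead
    predictions.  Includes residual-ratio selection of the number of modes, a
    spread sweep for the RBF width, RMSE/MAE/MSE evaluation, seeded synthetic
    generators (ECG-like waveforms, tone mixtures, Lorenz-63), WFDB format-212
    and CSV signal readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
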