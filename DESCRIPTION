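Package: facemyo
Title: Facial-Action Surface EMG Decoding for Myoelectric Prosthesis Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and decoding pipeline for facial-action surface
    electromyography (EMG) used to drive a two-degree-of-freedom hand
    prosthesis. Provides a synthetic multi-channel scalp-EMG generator with
    class-specific spatial asymmetry and band-energy profiles, Butterworth
    band-pass and mains notch preprocessing, FFT band-energy and
    Daubechies-5 wavelet subband-energy features, a log-sigmoid feed-forward
    classifier trained by Levenberg-Marquardt damped Gauss-Newton updates
    (with an Adam baseline), stratified repeated k-fold evaluation with the
    accompanying comparison statistics, and an online decision-window
    simulator that maps recognized actions to prosthesis commands through a
    saturating hand/wrist state machine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
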