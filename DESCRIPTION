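Package: hemowave
Title: Wave Intensity and Input Impedance Analysis of Aortic
    Pressure-Flow Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for invasive aortic hemodynamics: ECG
    R-wave gated beat segmentation and eight-beat ensemble averaging,
    Fourier input impedance with characteristic impedance (mean modulus
    over 1-10 Hz), linear forward/backward pressure wave separation with
    reflection magnitude and reflection index, wave intensity analysis
    (W1, W2 and the mid-systolic negative wave), stiffness parameter
    beta, fractional diameter change and Bramwell-Hill local pulse wave
    velocity, plus paired Wilcoxon signed-rank and Pearson correlation
    reporting for small animal cohorts.  Includes a single-tube
    transmission-line waveform simulator with known characteristic
    impedance, reflection coefficient and reflection delay for
    validation against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
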