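Package: sfdcm
Title: Dynamic Causal Modelling of Spontaneous Skin Conductance Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A generative (forward) model of how sudomotor nerve activity
    (SNA) bursts produce spontaneous fluctuations (SF) in skin conductance,
    together with variational Bayesian inversion to recover burst timings
    and amplitudes from observed conductance traces. Bursts are modelled as
    Gaussian bumps driving a third-order linear ordinary differential
    equation whose impulse response is the canonical SF waveform. The
    package also provides the surrounding toolchain: Butterworth
    pre-processing and epoch segmentation, estimation of a canonical
    response function by finite impulse response deconvolution, fitting of
    the ODE kernel to a response function, burst counting with validity
    statistics (Pearson and point-biserial correlation, ROC curves, nested
    regression F-tests), and a seeded synthetic-study generator so that
    every stage can be exercised without laboratory data.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
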