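Package: lvcontrol
Title: Laguerre-Volterra Modeling and Inverse-Model Control of Evoked Neural Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear input-output modeling of amplitude/interval event-train
    data with second-order Volterra series compressed on the discrete
    orthonormal Laguerre basis, and model-based derivation of stimulation
    amplitudes by analytic inversion of the fitted model. Provides
    least-squares estimation of Laguerre-Volterra coefficients from
    (time, amplitude, response) event sequences, Volterra kernel
    reconstruction, leave-one-train-out cross-validation, a recursive
    per-event quadratic inverse solver that converts a desired response
    trajectory into stimulation amplitudes, generators for the standard
    random-interval stimulation protocols (fixed-amplitude and
    Gaussian-amplitude Poisson trains), and validation metrics (variance
    accounted for, normalized mean-square error, quantile-quantile
    comparison).
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
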