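Package: wavegate
Title: Traveling-Wave Gating and Inverse Input Design in Critical Unitary
    Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator for single-layer convolutional recurrent neural
    networks with unitary coupling kernels and a phase-preserving complex
    sigmoid activation. The coupling kernel is the convolutional exponential
    of a compact anti-Hermitian generator, so all linearization eigenvalues
    lie on the unit circle and the quiescent state is critical (marginally
    stable). A constant input can pattern the ongoing activity so that the
    local slope of the activation -- the attenuation map Gamma -- takes any
    prescribed spatial profile; the package implements the closed-form
    inversion from a desired Gamma to the constant input that realizes it,
    for both convolutional and dense (nonconvolutional) couplings. On top of
    this core it provides the linearized perturbation dynamics, the
    closed-form resonant response to point forcing, pattern generators for
    wave-gating experiments (attenuation bands, boxes with walls, labyrinths
    from band-passed noise, rotating annuli), flood-fill and synchrony
    diagnostics, Anderson-localization diagnostics for disordered 1D
    couplings, and scripted demo runners.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
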