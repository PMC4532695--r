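Package: lileyChaos
Title: Lyapunov Spectra and Four-Dimensional Chaos in the Liley Mean-Field EEG Model
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the macrocolumnar (spatially homogeneous) Liley
    mean-field model of the electroencephalogram, a system of ten coupled
    nonlinear ordinary differential equations for mean soma potentials and
    second-order synaptic kinetics.  Computes partial Lyapunov spectra with
    a reduced augmented tangent system (continuous Gram-Schmidt
    orthonormalization) and with a discrete QR-renormalization backend,
    classifies attractors by topological and Kaplan-Yorke dimension,
    detects four-dimensional chaos (a single positive exponent with
    topological dimension three), and maps its extent over the plane of
    thalamo-cortical input pulse densities.  Ships benchmark dynamical
    systems with analytically known spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    ggplot2,
    RcppTOML,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
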