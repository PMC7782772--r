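Package: soundlift
Title: Cortical-Inspired Sound Reconstruction via Heisenberg Lifts and
    Delayed Wilson-Cowan Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs degraded sounds with a model of the primary
    auditory cortex. A signal is mapped to its short-time Fourier
    representation, lifted to an augmented time-frequency-chirpiness
    space carrying a Heisenberg group structure, evolved by a delayed
    Wilson-Cowan integro-differential equation whose interaction kernel
    is the closed-form hypoelliptic (Kolmogorov) transition density of
    the chirp dynamics, then projected back and inverted to audio.
    Includes generators for synthetic chirp test signals, sparse
    truncated-kernel interaction operators, a Monte-Carlo validation of
    the kernel against its stochastic differential equation, and
    reproductions of the gap-bridging and chirp-crossing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
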