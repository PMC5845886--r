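Package: convcascade
Title: Filter Cascade Models of Early Visual Processing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates filter-based models of early visual processing (retinal
    ganglion cells, direction-selective and V1-like cells) as cascades of 3D
    spatio-temporal linear filters, recursive (IIR) filters, pointwise
    nonlinearities, contrast gain control via shunting inhibition, and leaky
    integrate-and-fire spike generation. Any model parameter (or the stimulus
    itself) can be fitted to data by gradient-based optimization using
    hand-derived reverse-mode gradients checked against finite differences.
    Includes seeded stimulus generators (chirp, gratings, checkerboard flicker,
    moving bars, noise, Poisson event trains), a VirtualRetina-dialect XML
    configuration reader, npy/CSV/JSON input-output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
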