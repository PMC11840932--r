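Package: ftirbind
Title: FTIR Band Analysis and Binding-Distance Modelling for Protein-DNA
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Fourier-transform infrared (FTIR)
    spectra of a [4Fe4S] DNA-repair glycosylase (Endonuclease III), double
    stranded DNA, and their complex. Provides a synthetic spectrum
    generator with the documented band inventory, baseline correction,
    Savitzky-Golay second-derivative peak detection, cross-spectrum band
    matching, an inverse-law frequency-shift-to-binding-distance model
    with ridge and neural-network regressors, binding thermodynamics
    (Gibbs energy, entropy from a dissociation constant), and [4Fe4S]
    cluster geometry plus protein-DNA distance extraction from PDB
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
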