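Package: sersim
Title: Coupled-Dipole Near-Field Simulation and SERS Spectral Analysis of
    Cytochrome c
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study surface-enhanced Raman scattering (SERS) of
    heme proteins near silver nanostructured surfaces. Implements a
    coupled-dipole simulator of the electric near field above ensembles of
    silver nanoparticles resting on a silver substrate (Mie dipole
    polarizabilities, image-method substrate coupling, plane-wave
    illumination at arbitrary incidence and polarization), and a Raman
    spectral pipeline for mitochondrial cytochrome c: a curated marker-band
    library for oxidized and reduced states, spline-knot baseline
    subtraction, band-intensity ratios, redox-state classification, and a
    synthetic-spectrum generator emulating redox mixtures and
    uncoupler/inhibitor treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
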