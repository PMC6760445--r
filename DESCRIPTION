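Package: microedtools
Title: MicroED Movie Conversion, Diffraction Geometry and Dose Analytics
Version: 0.1.0
Authors@R: person("MicroED", "Tools", email = "microed@example.org", role = c("aut", "cre"))
Description: Tools for handling continuous-rotation microcrystal electron
    diffraction (MicroED) movies from direct electron detectors. Reads MRC2014
    and TIA/SER movie stacks, applies a pedestal/clipping policy that preserves
    negative readout-noise excursions, and writes SMV diffraction images with
    headers derived from the acquisition geometry. Includes diffraction-geometry
    calculators (relativistic electron wavelength, detector-edge resolution,
    spot separation, exposure ledgers), Poisson background gain estimation,
    reflection merging statistics under tetragonal Laue symmetry (completeness,
    multiplicity, R_merge, CC1/2), shared exponential dose-decay fitting with
    D50, rocking-curve fitting, and a ground-truth diffraction-movie simulator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
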