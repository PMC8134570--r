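Package: fanxrd
Title: Digital Twin of a Fan-Beam Coded-Aperture X-Ray Transmission and
    Diffraction Imager
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and reconstruction for a fan-beam
    coded-aperture X-ray imaging system that acquires co-registered
    transmission and diffraction (XRD) data. Provides source-spectrum
    synthesis and filtration, material attenuation, binary coded-aperture
    generation, a sparse system-matrix forward model for encoded coherent
    scatter, Poisson maximum-likelihood (MLEM) spectral reconstruction,
    synthetic phantoms and reference momentum-transfer spectra, and the
    derived image products and characterization metrics (mean-q
    colorization, TQC images, hyperspectral q windows, spectrum
    cross-correlation, FWHM-based resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
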