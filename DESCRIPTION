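Package: fcoat
Title: Fast Multidither Coherent Optical Adaptive Wavefront Correction Through Scattering Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for binary-phase wavefront shaping
    through scattering media with the fast multidither coherent optical adaptive
    technique (fCOAT). Provides synthetic scattering media (complex Gaussian
    transmission matrices and random phase screens with an exponential
    decorrelation clock), a calibrated Fourier-optics forward model for a
    segmented binary spatial light modulator, frequency-multiplexed square-wave
    dithering with DFT demodulation and two-half phase retrieval, focus quality
    metrics (peak-to-background ratio, FWHM, position error), and a synthetic
    wide-field calcium-imaging generator with ROI-based dF/F quantification for
    focus-versus-speckle photostimulation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
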