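Package: specoct
Title: Spectroscopic Visible-Light Optical Coherence Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spectral-domain visible-light optical
    coherence microscopy (OCM) of brain tissue. Provides spectral-domain
    reconstruction (k-space resampling, background removal, numerical
    dispersion compensation, Fourier transform, surface detection, en-face
    projection), a constant-axial-resolution Gaussian-window spectroscopic
    toolbox with sub-band energy normalization, RGB and two-channel
    composition, global (per A-scan exponential fit) and local (per pixel,
    Vermeer-type) attenuation coefficient estimation, and the region-level
    statistics used to separate white matter, grey matter and amyloid-beta
    plaques. A seeded synthetic interferogram generator with layered
    phantoms and full ground truth makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
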