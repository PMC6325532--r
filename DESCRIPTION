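Package: stripequant
Title: Quantification of Stripe Artifacts in Gaussian and Bessel Beam
    Light-Sheet Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for quantifying shadow ("stripe")
    artifacts in light-sheet microscopy of cleared tissue. Provides
    closed-form Gaussian and axicon-generated Bessel beam optics with an
    angular-spectrum wave-propagation oracle; a physics-grounded synthetic
    generator of paired Gaussian/Bessel acquisitions of a brain-like
    phantom with known obstacle-induced stripes; a Fourier-domain
    directional stripe estimator reporting striped area as a percentage of
    brain area with a Gaussian-fit volume summary; a paired line-profile
    "bar code" streak metric with threshold sensitivity sweep; and a
    colocalization comparison (rigid registration, gamma adjustment,
    IsoData auto-thresholding, Manders coefficients, paired t test)
    between the two illumination modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
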