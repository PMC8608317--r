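Package: hazvis
Title: Hazard Visibility Scoring for Low-Vision Architectural Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the visibility of architectural hazards (steps, curbs,
    walkway edges) to observers with reduced visual acuity and contrast
    sensitivity. A parametric contrast sensitivity function built from
    clinical logMAR acuity and Pelli-Robson contrast sensitivity drives a
    band-threshold filter that removes image content below the observer's
    perceptual threshold; luminance boundaries extracted from the filtered
    image are matched against ground-truth geometric edges to produce a 0-1
    Hazard Visibility Score (HVS) per region of interest. Includes a
    synthetic walkway/step scene generator with pinhole projection and
    Lambertian shading, simulated forced-choice observers, and the
    psychophysical validation statistics (logistic regression of
    identification accuracy on HVS, deviance accounting, likelihood-ratio
    and Chow tests, slope-versus-vision meta-regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
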