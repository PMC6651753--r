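Package: gridlime
Title: Superpixel and Square-Grid LIME Explanations for Image Patch
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Local surrogate (LIME-style) explanations for black-box
    image-patch classifiers, aimed at histopathology patches in the
    Patch Camelyon convention (96x96 RGB, tumor label decided by the
    central 32x32 window). Perturbs an image by blacking out segments,
    queries the classifier on the perturbed distribution, and fits a
    linear surrogate whose per-segment weights form an attribution heat
    map. Provides interchangeable superpixel backends (Felzenszwalb,
    SLIC, quickshift via scikit-image), a parameter-free multi-scale
    square-grid attribution scheme with summed heat maps, cross-backend
    averaged maps, symmetric diverging-colormap rendering with
    annotation overlays, a synthetic patch generator with deterministic
    mock classifiers for testing, and analytic trainable-parameter
    counting for the reference CNN architectures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python 3 with numpy, imageio and scikit-image on
    the PATH (only for the slic/quickshift/felzenszwalb segmentation
    backends; squaregrid needs none).
Config/testthat/edition: 3
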