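Package: calfdepth
Title: Dorsal Depth-Image Morphometrics and Body-Weight Prediction for Dairy Calves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based segmentation of top-down depth scenes of pre-weaned
    dairy calves (hue thresholding, morphological cleanup, template shape
    matching with area and bounding-box filters), extraction of body metrics
    (width, length, contour area, average height, volume) from depth maps,
    mask evaluation (IoU, Dice, pixel accuracy) with ANOVA/Tukey comparisons,
    Pearson correlation structure analysis across age quartiles with Mantel
    tests, and body-weight prediction by calf-grouped cross-validation
    (linear model, gradient-boosted trees with randomized hyperparameter
    search) and time-forward longitudinal forecasting with a random-intercept
    mixed model. A synthetic-scene and synthetic-herd generator emulates the
    farm recordings so the full pipeline is testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    mgcv,
    lme4,
    xgboost,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
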