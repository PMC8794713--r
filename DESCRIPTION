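Package: larkscape
Title: Foraging Habitat Selection and Central-Place Foraging Analysis for
    Farmland Songbirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for foraging-habitat selection by
    chick-provisioning farmland songbirds observed from the nest: fixed-radius
    home ranges from a nest-weighted distance percentile, distance-weighted
    habitat availability, pseudo-absence resource-selection modelling with
    penalized-spline additive models and permutation variable importance,
    randomization-based compositional analysis of use versus availability,
    per-habitat seasonal-use mixed logistic models, and foraging parameters
    (feeding frequency, flight distance, 95% minimum convex polygons) with
    their seasonal trend models.  A synthetic-data generator with known
    ground truth (central-place foraging with an exponential distance kernel
    over a crop mosaic) makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    mgcv,
    glmmTMB,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
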