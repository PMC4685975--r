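Package: lactiodine
Title: Feed-to-Milk Iodine Transfer Models and Dietary Iodine Intake
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the iodine concentration of cow milk from the iodine
    content of the feed ration and its goitrogen load (glucosinolate intake or
    rapeseed cake/meal inclusion), using two published log-scale cubic transfer
    models, and inverts them to find the feed iodine supplementation needed to
    reach a target milk concentration. Re-implements the model-construction
    machinery (polynomial candidate terms to order 3, p-value stepwise
    selection, OLS inference on the log response, study-effect screening and
    leave-one-out cross-validation), provides a synthetic treatment-mean
    generator with the statistical structure of the source literature
    compilation, and chains milk iodine concentrations through Norwegian dairy
    consumption profiles to per-group iodine intake and percent of the
    recommended daily intake.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
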