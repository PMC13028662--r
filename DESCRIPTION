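Package: maeopt
Title: Response-Surface and Machine-Learning Optimization of Microwave-Assisted Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing microwave-assisted extraction of phenolic and
    flavonoid compounds from plant press residues. Implements Box-Behnken
    experimental design construction and coded-factor arithmetic, full
    second-order response-surface fitting with ANOVA and lack-of-fit testing,
    a k-nearest-neighbour regressor supporting eleven distance metrics and
    three distance-weighting schemes, single- and multi-objective dragonfly
    swarm optimizers with a Pareto archive, dragonfly-driven KNN
    hyperparameter tuning, desirability-based multi-response optimization,
    and a synthetic-data generator for parameter-recovery studies. Ships the
    27-run Box-Behnken dataset for Opuntia ficus-indica seed press residue
    extraction together with the published model predictions and validation
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
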