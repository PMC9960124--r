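Package: breathratio
Title: Exhaled-Breath VOC Ratio Analysis and Diagnostic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of volatile organic compound (VOC)
    peak tables from thermal-desorption GC-MS exhaled-breath studies. Implements
    ambient-air background subtraction, detection and occurrence filtering,
    ratio-feature construction against high-occurrence denominator compounds,
    Spearman rank-correlation screening against clinical factors with
    confounder exclusion, correlation power analysis, and two from-scratch
    diagnostic classifiers (gradient-boosted decision trees with relative
    variable importance, and a small multilayer perceptron trained by BFGS),
    together with a synthetic cohort generator with injectable rank-correlation
    effects so every stage can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
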