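Package: foodmats
Title: Food and Beverage Marketing Assessment Tool for Settings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Food and beverage Marketing Assessment Tool for
    Settings (FoodMATS), an observational audit instrument for food and
    beverage marketing in recreation and sport facilities. Provides the audit
    data model and CSV/JSON schemas, rule-based healthfulness and size
    classification, the exposure-power-repetition site scoring algorithm,
    inter-rater reliability statistics (percent agreement, Cohen's kappa,
    weighted kappa, two-way random intraclass correlation) with confidence
    intervals and interpretation bands, a validity pipeline (outlier
    truncation, Pearson/Spearman/partial correlations, sequential regression
    with R-squared-change F tests, collinearity screening), and a seeded
    synthetic-data generator for audits, rater pairs, sponsorship and sales
    with known ground-truth structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
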