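Package: mcakm
Title: Risk-Factor Clustering for Rare Outcomes via Multiple
    Correspondence Analysis and Cross-Validated K-Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers groups of categorical risk factors associated with
    rare binary outcomes by embedding category levels in Euclidean space
    with multiple correspondence analysis (indicator or Burt basis) and
    clustering the category coordinates with a k-means algorithm whose
    number of clusters is chosen by v-fold cross-validated clustering
    cost.  Includes a synthetic claims-cohort generator with plantable
    category associations, an ICD-9-CM cohort construction filter with a
    repeated-diagnosis confirmation rule, and a logistic-regression
    control arm with explicit quasi-separation diagnostics for the
    rare-event setting in which maximum-likelihood estimates break down.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
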