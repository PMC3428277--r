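Package: adirshort
Title: Shortened ADI-R Autism Screening with Alternating Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying item reduction in the Autism Diagnostic
    Interview-Revised (ADI-R). Encodes and recodes 93-item ADI-R answer
    sheets, applies the instrument's domain-cutoff diagnostic algorithm,
    trains an alternating decision tree (ADTree) boosting classifier whose
    signed score separates autism from non-spectrum with
    amplitude-as-confidence semantics, evaluates classifiers by stratified
    cross-validation, and generates synthetic case/control cohorts together
    with two control simulators (observed-pool resampling and constrained
    near-cutoff sheets) for specificity experiments under class imbalance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
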