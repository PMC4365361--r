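Package: docdiag
Title: Degree-of-Confidence Encoding of Incomplete Clinical Records for
    Diagnostic Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes tabular clinical records whose cells may be exact
    values, intervals, or unknown against declared attribute domains;
    computes per-attribute and per-record Degrees of Confidence (DoC) and
    Quality-of-Information (QoI) scores; ships a schizophrenia screening
    schema (age/sex and genetic predisposition lookups, lucidity and
    differential products, Kurt Schneider first- and second-order symptom
    scores); generates labelled synthetic patient populations with a
    documented planted risk rule; and trains a small feed-forward neural
    classifier whose two outputs are a disease likelihood and a confidence
    value.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
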