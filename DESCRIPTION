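Package: micereport
Title: Rule-Based Mining of Mouse Sex and Age Reporting in Full-Text Articles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies mentions of mouse sex and age in full-text
    biomedical articles with a transparent, user-editable rule set; unifies
    per-document candidate mentions into one document-level annotation per
    characteristic (longest span, earliest offset on ties); scores annotations
    against a gold standard with document-level precision, recall and F-score;
    and computes corpus-level reporting statistics (reporting breakdowns and
    trends, sex-bias ratios, a binomial proportion test with confidence
    interval, two-way ANOVA without replication, Spearman rank correlations
    and a per-journal reporting index). Ships a seeded synthetic-corpus
    generator with known gold annotations and configurable hard-case
    distractor sentences so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
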