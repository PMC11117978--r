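Package: glp1signal
Title: Pharmacovigilance Signal Detection for GLP-1 Receptor Agonists
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for descriptive and disproportionality analysis of
    spontaneous adverse-event reports (Individual Case Safety Reports) on
    glucagon-like peptide-1 receptor agonists, centred on semaglutide.
    Provides a MedDRA-style term vocabulary grouping dose-error and
    off-label-use preferred terms into four high level terms, a line-listing
    data model with study filters, stratified characteristics tables,
    system-organ-class and high-level-term frequency summaries, reporting
    odds ratios with Woolf confidence intervals and signal classification,
    a seeded synthetic report generator with plantable true odds ratios,
    and relative-search-volume normalization utilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    tidyr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
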