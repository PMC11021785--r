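Package: dilinet
Title: Pharmacovigilance Signal Detection and Drug-Gene Network Analysis for
    Drug-Induced Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for spontaneous-report
    pharmacovigilance of drug-induced liver injury (DILI). Implements
    disproportionality analysis by reporting odds ratio (ROR) with Woolf
    confidence intervals and the standard signal rule (at least three reports
    and lower 95% CI bound above 1), query expansion over a PT/HLT/SMQ
    dictionary hierarchy, case-level deduplication of report versions,
    cohort characterisation with time-to-onset quartiles, drug-target and
    disease gene-set intersection, score-thresholded protein-protein
    interaction networks with degree-ranked hubs, and hypergeometric pathway
    over-representation with Benjamini-Hochberg adjustment. A synthetic
    spontaneous-report generator with planted odds ratios, duplicate case
    versions and configurable missingness provides ground truth for every
    stage, so the whole pipeline is testable without access to any external
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
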