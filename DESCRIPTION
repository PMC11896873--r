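Package: txscreen
Title: Transporter Inhibitor and Substrate Screening with Graph Neural
    Networks and Similarity Searching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based profiling of chemical-transporter interactions.
    Standardizes SMILES datasets (validity checking, canonicalization, salt
    stripping, deduplication), trains directed message-passing neural
    network (D-MPNN) ensemble classifiers for well-populated transporter
    targets, applies maximum-Tanimoto similarity screening against
    reference compound sets for data-poor targets, scores every prediction
    with the sum of distance-weighted contributions (SDC) applicability
    domain, and emits per-compound by per-target inhibitor/substrate
    profiles. Includes cross-validation, scaffold-split evaluation, ROC/PR
    metrics, and a seeded synthetic SMILES generator so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
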