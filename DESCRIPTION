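Package: indelrules
Title: Interpretable Rule Learning for Protein Indel Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates non-frameshifting protein insertions and deletions
    (NFS-Indels) with categorical structural, functional, physico-chemical
    and evolutionary parameters, selects discriminative parameters by a
    frequency-difference statistic with a categorical-association filter,
    learns human-readable deleterious/neutral classification rules by a
    sequential-covering (propositional ILP-style) algorithm, and evaluates
    rule sets by stratified cross-validation with standard confusion-matrix
    statistics. A synthetic-data module generates labelled feature tables
    with planted rules and artificial protein annotation tracks so the whole
    pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
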