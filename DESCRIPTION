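Package: polypharm
Title: Harmonized Drug-Target Association Databases with Selectivity
    Scoring and Structure-Aware Queries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes heterogeneous drug-target evidence (quantitative
    potency tables and curated qualitative associations) into a scored
    association database. Potencies are normalized to pChEMBL
    (-log10 molar), structures are standardized and consolidated under
    internal identifiers, and every molecule-target pair is scored with a
    mean pChEMBL, a known selectivity index, and an evidence-count
    confidence z-score. The resulting database supports fingerprint-based
    Tanimoto similarity search, multi-target queries, bipartite
    drug-target network export, local gene-set enrichment of target
    lists, and correlation of structural similarity with drug response in
    cell-line screening data. A deterministic fixture generator produces
    synthetic source tables with independently computed ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
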