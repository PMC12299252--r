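Package: screenclean
Title: Accuracy-Boosting Bioactivity Data Curation and Virtual-Screening Triage
Version: 0.1.0
Authors@R: person("screenclean", "developers", role = c("aut", "cre"),
    email = "maintainers@screenclean.dev")
Description: Toolkit for curating multi-assay bioactivity tables ahead of
    QSAR modelling and for triaging virtual-screening output. Implements
    standard cleaning (SMILES standardization, pIC50 normalization, null and
    exact-duplicate handling), molecular-weight filtering, an assay-aware
    selective-cleaning duplicate-resolution algorithm, Bemis-Murcko scaffold
    and random splitting, a pluggable cross-validated regression benchmark for
    comparing curation strategies, a potency/affinity hit-triage gate with
    structural admissibility rules, docking-score consensus ranking with
    pocket-selectivity deltas, interaction-energy classification, and a
    synthetic multi-assay data generator with known ground truth. Chemistry
    primitives are computed through a bundled RDKit helper invoked via the
    system Python.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, discoverable as 'python' on
    the PATH or via options(screenclean.python=...)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
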