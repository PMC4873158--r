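Package: pathconcord
Title: Cross-Study Concordance and Co-Expression Networks for Immune Signaling Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing blood transcriptional profiles of curated
    signaling pathways (e.g. Toll-like, T-cell and B-cell receptor signaling)
    across independent case/control or paired two-timepoint expression studies.
    Provides per-gene Welch and paired t statistics, permutation tests for
    enrichment of differentially expressed genes within gene sets, Pearson
    concordance of t statistics between studies, weighted co-expression
    networks built from topological overlap (TOM) with soft-threshold
    selection, permutation-FDR edge calling and hub connectivity, and
    correlation of a designated regulator gene (such as DNMT1) with pathway
    genes. A parameterized multi-cohort simulator with planted effects, hub
    structure and a coupled regulator supports end-to-end validation, and a
    pipeline driver produces machine-readable report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
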