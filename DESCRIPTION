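Package: MDSCscreen
Title: Composite Fold/Influence-Factor/Distance Prioritization of
    TGF-beta-Responsive Genes in MDSC Subsets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-subset differential-expression
    prioritization pipeline for myeloid-derived suppressor cells
    (Mo-MDSC and Gr-MDSC) treated with TGF-beta. Per-gene log2 fold
    changes in the two subsets are combined into a composite Fold
    statistic (their sum), an Influence Factor (Fold times the Mo minus
    Gr difference, encoding which subset responded more strongly) and a
    Distance from the origin of the (Fold, IF) plane. Genes passing an
    absolute Fold screen are partitioned into six groups by the IF sign
    and magnitude, the top genes per group by Distance are selected,
    and the candidate list is re-ranked from qPCR delta-delta-Ct
    relative expression. A seeded synthetic-experiment generator with
    planted effects supports recovery testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, DifferentialExpression, Software
RoxygenNote: 7.3.3
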