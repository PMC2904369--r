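Package: iqtlmap
Title: Mapping Transgenerational Imprinted QTLs in Reciprocal F2 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Interval mapping of imprinted quantitative trait loci (iQTLs)
    whose parent-of-origin effects are transmitted across generations. A
    two-stage reciprocal cross between two inbred lines yields four
    epigenetically distinct F2 families; the 16 ordered-genotype means across
    those families are decomposed into an overall mean, F1-expressed maternal
    and paternal imprinting effects, F2-expressed additive, dominance and
    imprinting effects, and their cross-generation interactions. The package
    fits the marker-conditional normal-mixture likelihood by EM under
    arbitrary zero constraints, provides the hierarchy of likelihood-ratio
    tests for imprinting expressed in each generation, performs genome scans
    with permutation thresholds, and includes a simulator for power and
    estimation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
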