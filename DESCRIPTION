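Package: weightedDGE
Title: Assumption-Free Weighted Differential Expression for Single-Cell and
    Spatial RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential gene expression for UMI count data without
    distributional assumptions. Each cell (or spatial bin) receives a
    per-gene statistical weight derived from an intracluster correlation
    coefficient estimated directly from the counts, following the theory of
    cluster-randomized experiments. Weighted means are compared with a
    weighted Welch-type t-test and supplemented by an aggregate-count
    chi-squared test, with conservative rules for combining the two
    p-values. Includes replicate-aware multi-sample testing with
    inverse-variance sample weights (a model-free alternative to
    pseudo-bulk), a bin-level spatial mode, standard comparator tests
    (Wilcoxon rank-sum, unweighted t on relative or log-normalized counts),
    and simulation machinery for benchmarking: binomial UMI thinning,
    a calibrated uniform noise model, proportional upregulation, and a
    ground-truth-bearing synthetic count-matrix generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
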