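Package: gonadtx
Title: Knockout Gonad Transcriptome Analysis for Allotetraploid Frogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression and transcriptome-sexualization analysis
    of knockout versus wildtype gonad transcriptomes in an allotetraploid frog.
    Provides a seeded negative-binomial simulator of two-subgenome count
    matrices mirroring a 42-tadpole knockout study design, count-matrix I/O
    with a mean-count abundance filter, a self-contained negative-binomial
    GLM differential-expression stage with batch covariates and
    Benjamini-Hochberg FDR calling, consensus and sex-biased-gene
    intersection summaries, subgenome (L/S) bias assessment with an exact
    binomial test, a permutation test for transcriptome masculinization or
    feminization over a 90-gene sex-related panel, and histology statistics
    (pixel proportions, pooled one-tailed t-tests from raw values or printed
    summaries, Cohen's d and U3, hemacytometer sperm concentration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
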