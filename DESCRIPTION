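Package: degpag
Title: Joint Identification of Differentially Expressed and
    Phenotype-Associated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies genes that are simultaneously differentially
    expressed between two treatment groups and linearly associated with a
    continuous phenotype.  The core is an intersection-union likelihood
    ratio test on the per-gene Gaussian linear model
    expression ~ group + phenotype with the composite null "no group
    effect OR no phenotype effect", referred against a chi-square(1)
    upper tail.  Comparator two-stage strategies (naive intersection and
    hierarchical screening), component tests (pooled two-sample t-test,
    the SAM fudge-factor statistic with permutation FDR, and
    phenotype-on-expression regressions with and without a group
    covariate), Bonferroni and Benjamini-Hochberg corrections, and a
    seeded simulation engine for type-I-error and power studies are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
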