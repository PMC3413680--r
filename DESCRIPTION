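Package: relexp
Title: Selection of Relevant Transcriptomics Experiments for
    Guilt-by-Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects, from a large collection of transcriptomics
    experiments, the subset most relevant to a given gene functional
    category (a GO or MIPS FunCat term, or a KEGG pathway).  Relevance is
    defined through the discriminatory ability of Pearson correlation: an
    experiment subset is good when within-category gene-pair correlations
    are significantly higher than category-versus-background correlations,
    as measured by a two-sample t-test.  The package implements a greedy
    seed-and-grow search over experiment subsets, correlation significance
    via the t-transform and Fisher z confidence bounds, an evaluation
    framework based on ROC analysis under ten-fold cross-validation (pair
    classification and guilt-by-association gene function prediction), an
    annotation-specificity sweep over nested category chains, and a
    synthetic expression generator that plants known relevant experiments
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
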