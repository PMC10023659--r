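Package: sigconfound
Title: Disentangling Antipsychotic-Drug and Disease Effects in Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for separating antipsychotic-drug (APD)
    treatment effects from schizophrenia-associated effects in bulk brain
    RNA-seq. Implements per-sample disease-expression-signature scoring
    (projection of covariate-corrected logCPM residuals onto case-control
    log fold changes), covariate selection and residualization, signed
    two-dataset consensus co-expression modules with convergent/divergent
    classification against a drug-exposure dataset, reference-based
    cell-type deconvolution, Fisher's exact gene-set enrichment, and
    non-parametric group testing. Ships a synthetic-cohort generator that
    emulates the statistical structure of a toxicology-stratified
    case-control study paired with a primate drug-treatment study, so the
    whole analysis graph is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    edgeR,
    limma,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
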