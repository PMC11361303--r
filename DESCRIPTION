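Package: commstate
Title: Longitudinal Gut Microbiome Community-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for longitudinal analysis of gut microbiome community
    states across multiple omics layers. Implements Dirichlet multinomial
    mixture (DMM) community typing with Laplace-evidence model selection,
    a transition-frequency null model with chi-square goodness-of-fit and
    standardized residuals, intra- versus inter-individual dissimilarity
    partitioning, per-feature variance-component and intraclass-correlation
    decomposition with cross-layer comparisons, compositional log-ratio
    association testing against metabolite panels, and a synthetic
    three-layer cohort generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    lme4,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
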