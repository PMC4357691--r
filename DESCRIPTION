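Package: cmi2ni
Title: Gene Regulatory Network Inference with Conditional Mutual Inclusive Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reverse-engineering of gene regulatory networks from expression
    matrices with conditional mutual inclusive information (CMI2), a
    Kullback-Leibler based association measure that averages the divergence
    between the joint distribution and the two interventional distributions
    obtained by severing a putative edge in either direction. Provides
    closed-form Gaussian estimators for mutual information, conditional
    mutual information, causal strength and CMI2; a path-consistency
    inference engine with pluggable association measures (CMI2, CMI, partial
    correlation); confusion-matrix and ROC/AUC evaluation against
    DREAM-style gold standards; a linear-Gaussian structural equation
    simulator with analytic population covariances for benchmarking; and
    readers, writers and a command-line interface for tab-separated
    expression and edge-list files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
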