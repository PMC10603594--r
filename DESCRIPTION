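Package: fatemap
Title: Mapping Cell Fates to Parametric Conditions by Systematic Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Constructs maps between the stable steady states (cell fates) of
    ODE gene-network models and their kinetic parameters. All parameters are
    perturbed at random, stable steady states are enumerated by multi-start
    integration with Newton polishing, monostable states are clustered into
    fate classes, principal component analysis reduces the state space, and
    partial least-squares regression of the leading principal component on the
    parameters yields confidence-interval classification rules that predict
    the fate reached under a new parameter set. Multistable states are
    assigned by a critical value on PC1 or by confidence ellipses on the
    PC1-PC2 plane, a kernel support vector machine predicts mono- versus
    multistability from parameters alone, and variable-importance-in-projection
    scores rank the parameters driving each fate. Toggle-switch and
    epithelial-mesenchymal-transition network models ship as built-ins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    kernlab,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
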