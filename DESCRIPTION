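Package: ctlasso
Title: Clustered-LASSO Regularization for Cell-Type Specific ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which mechanistic parameters of an ordinary
    differential equation model are shared between which subsets of cell
    types. The same model structure is replicated across n cell types with
    log10 fold-change parameters relating each cell type to a technical
    reference; all pairwise differences of fold changes are penalized with
    an L_q pseudonorm (clustered LASSO), which makes the result independent
    of the reference choice and lets cell types cluster into groups sharing
    a parameter value. Includes forward-sensitivity ODE integration, an
    adapted Levenberg-Marquardt trust-region optimizer that handles the
    nonsmooth penalty (step truncation at sign changes, manifold detection,
    sensitivity merging and release), and two-step model selection via a
    lambda scan with constrained refits and likelihood-ratio tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
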