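Package: scratchpde
Title: Weak-Form PDE Discovery and Refinement for Scratch-Assay Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers advection-diffusion-reaction models of collective cell
    migration and proliferation from scratch (wound-healing) assay density
    fields. Cell-centroid tables are binned and smoothed into density fields;
    a weak-form (variational) operator library built on piecewise-linear
    finite elements is sparsified by greedy stepwise regression with
    elbow-based model selection; selected coefficients are refined by
    PDE-constrained optimization with discrete-adjoint gradients; and
    post-inference sensitivity is quantified by loss-contour scans and a
    local Gaussian (Laplace) approximation. A synthetic scratch-assay
    generator with Poisson count sampling provides ground-truth datasets so
    the whole pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
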