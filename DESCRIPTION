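Package: pombesize
Title: Stochastic Cell-Size Dynamics and Size-Control Inference for Fission Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models cell-size homeostasis in fission yeast
    (Schizosaccharomyces pombe) with a piecewise deterministic Markov
    process in which the cell cycle is divided into N effective stages,
    growth follows a three-phase pattern (exponential elongation, growth
    arrest during septation, rapid exponential reshaping), stage
    transitions occur at a size-dependent rate a*V^alpha, and division
    partitions size deterministically or by a beta-distributed ratio.
    Provides an exact stochastic simulator of cell lineages, closed-form
    lineage cell-size and birth-size distributions evaluated by numerical
    transform inversion, the deterministic large-N limit mixture,
    birth/division size correlations, and a distribution-matching
    pipeline that infers all model parameters (including the size-control
    strength distinguishing timer, adder and sizer strategies) from
    single-cell lineage time courses, with bootstrap standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
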