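Package: autolump
Title: Automated Proper Lumping of Linear Compartmental and PBPK Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model order reduction for linear compartmental systems, in
    particular physiologically based pharmacokinetic (PBPK) models, by
    automated proper lumping. Given a micro-rate-constant matrix, an output
    state and a tolerance on the relative difference in output AUC, the
    package searches for the smallest lumped model whose lumped rate matrix
    K_hat = M K M+ (with M a 0/1 lumping matrix and M+ its Moore-Penrose
    pseudo-inverse) reproduces the output exposure within tolerance. Four
    interchangeable inner search algorithms (full enumeration over set
    partitions, non-adaptive random search, scree-plot-initialised random
    search, and simulated annealing) run inside one incremental outer loop
    that grows the number of lumped states until the criterion is met.
    Includes matrix-exponential simulation, closed-form AUC, construction of
    rate matrices from physiological parameter tables, a bundled 17-state
    fentanyl-like example topology, and synthetic system generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
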