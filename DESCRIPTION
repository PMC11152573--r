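Package: rushkinetics
Title: Compartmental Kinetics of Synchronized Secretory Trafficking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling and quantifying synchronized secretory
    trafficking experiments (RUSH assays). Implements a linear compartment
    model of ER-to-Golgi-to-post-Golgi transport in which intra-organelle
    partitioning into ER exit sites and Golgi raft domains sets effective
    efflux rates, together with global multistart Levenberg-Marquardt
    fitting of the model to ER- and Golgi-release efflux curves,
    single-exponential half-time extraction, GPMV raft partition
    coefficient quantification, mask-based Pearson colocalization, and a
    seeded synthetic-data generator for efflux curves, line scans and
    image pairs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
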