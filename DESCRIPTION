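Package: sacsim
Title: Finite-Element Simulation of Spring-Assisted Cranioplasty for
    Sagittal Synostosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to study how calvarial bone properties, distraction
    spring characteristics and surgical settings shape the outcome of
    spring-assisted cranioplasty for sagittal synostosis.  The package
    procedurally generates a parametric synostotic infant skull as a
    labelled hexahedral shell mesh, simulates spring-driven skull
    expansion with a small-strain linear-elastic finite-element model,
    runs one-at-a-time parameter sweeps of the change in cranial index,
    fits power-law and linear surrogate models to the sweep output, and
    computes local sensitivity indices and pairwise difference curves
    from the fitted surrogates.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
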