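Package: kiwisim
Title: Biophysical Simulation of Kiwifruit Berry Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A process-based simulator of kiwifruit (Actinidia deliciosa)
    berry growth over the full season, from shortly after full bloom to
    harvest. The fruit is a single compartment exchanging water and
    sucrose with the stem vasculature through a pedicel/receptacle
    conduit, growing by turgor-driven plastic expansion with an elastic
    component, storing carbohydrate as starch that is hydrolysed late in
    the season, and losing water and dry matter by transpiration and
    respiration. Includes a synthetic seasonal/diurnal weather generator,
    a fixed-step fourth-order Runge-Kutta integrator with an embedded
    algebraic pedicel solve, one-at-a-time sensitivity analysis, and
    utilities for comparing simulated diurnal growth with dendrometer
    (LVDT) diameter records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
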