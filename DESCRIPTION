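Package: sansr
Title: Stochastic Resonance in Sinoatrial-Node Pacemaker Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study noise-assisted action-potential generation in
    sinoatrial-node (SAN) pacemaker cells. Provides a common-pool coupled-clock
    single-cell model (membrane currents plus sarcoplasmic-reticulum Ca cycling)
    with carbachol modulation and current injection; sine-wave and band-limited
    white-noise stimulus protocols; action-potential detection, firing metrics
    and one-to-one capture / resonance-spectrum analysis; two-parameter
    (g_CaL, P_up) firing-diagram sweeps; a 2-D gap-junction-coupled tissue model
    of sinus arrest and its rescue by noise; Ca-imaging analysis (global
    transient subtraction, local Ca-release detection, L-moment tail statistics,
    mean-excess curves, subthreshold Vm-Ca cross-correlation); and seeded
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
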