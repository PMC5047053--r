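Package: osteowave
Title: Layered-Tissue Ultrasound Propagation over a Fractured Cortical Plate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-dimensional elastodynamic finite-difference time-domain
    (FDTD) simulation of low-intensity therapeutic ultrasound crossing a
    soft-tissue stack (skin, fat, muscle) onto interrupted cortical plates
    that form a fracture gap, together with the receiver metrics used in
    quantitative bone ultrasound: time-of-flight of the first arriving
    signal (TOF_FAS, parabolic sub-sample onset), sound pressure level
    relative to a reference receiver, and windowed RMS amplitude. Also
    provides the statistical toolkit of the accompanying animal study
    (summary-based pooled t test, Mann-Whitney U with exact enumeration,
    Cohen's kappa, Lilliefors-type Kolmogorov-Smirnov normality with
    simulated p, Cohen's-d sample sizing, radiographic fracture scoring)
    and seeded synthetic-data generators for both arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
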