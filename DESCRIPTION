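Package: vtlocalizer
Title: Simulation-Driven Localization of Ventricular Tachycardia Exit Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale platform for non-invasive localization of
    post-infarct ventricular tachycardia (VT) exit sites. Generates
    parametric thick-walled ventricular meshes with rule-based fibers,
    simulates libraries of focal paced beats and figure-of-eight VT beats
    with an anisotropic graph-eikonal activation model, synthesizes 12-lead
    ECGs (plus four vector combinations) and 8-vector implanted-device
    electrograms through an infinite-volume-conductor pseudo-ECG forward
    model, and trains a multichannel time-series regressor with transfer
    learning to predict VT exit sites in universal ventricular coordinates.
    Includes rotating held-out evaluation scenarios with localization-error
    statistics and 17-segment AHA reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
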