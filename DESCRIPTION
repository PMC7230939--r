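Package: muos
Title: Transport Simulation and Collective-Migration Analysis for a
    Micro-Optic-Stalk Gradient Device
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the micro-optic-stalk (muOS) microfluidic device, a
    two-reservoir source/sink chamber pair joined by an array of tapered
    microchannels that mimics the Drosophila optic stalk. Provides a
    depth-averaged finite-volume solver for steady and transient
    diffusion-advection of a growth-factor (FGF) or dextran tracer,
    axial concentration profiles, gradient-region partitioning and
    linearity statistics; trajectory metrics for collectively migrating
    retinal neuroblast clusters (total path length, net displacement,
    directionality ratio) with size-class summaries; detection and
    regional localization of cluster fission (disaggregation) events and
    the small-cluster-fraction timeline; and a calibrated synthetic
    track generator (gamma step lengths, von Mises headings,
    concentration-gated fission) so the whole pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
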