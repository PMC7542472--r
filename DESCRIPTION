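Package: tumorshed
Title: Multicompartment Simulation of Vascularized Tumor Growth and
    Protein Shedding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic multicompartment model of vascularized tumor
    growth and plasma biomarker shedding. Tumor tissue is discretized into
    concentric cylindrical compartments around vasculature at single-cell
    radial resolution; an exponential oxygen gradient sets per-compartment
    birth and death rates interpolated from in vitro anchor conditions.
    Daily forward-Euler difference equations advance per-compartment
    populations with carrying-capacity overflow and inter-compartment
    motility, and a one-compartment plasma equation with first-order
    elimination converts per-compartment protein outflux (extracellular,
    proliferation-driven, or non-extracellular, necrosis-driven) into
    plasma mass trajectories. Includes parameter grid scans with validity
    selection, one-at-a-time sensitivity sweeps, per-compartment
    contribution decomposition, and protein parameter scans with
    dynamic-range envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
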