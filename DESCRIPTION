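Package: mofkinetics
Title: Uptake and Release Kinetics of Guest Molecules in Porous
    Metal-Organic Framework Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of guest-molecule loading and release by
    metal-organic framework (MOF) nanoparticles. Converts nanoparticle size
    and crystallographic density into per-particle mass and number densities,
    fits Langmuir sorption isotherms to depletion data and derives molar
    payloads, molecules per particle, weight-payload ratios and the surface
    area occupied per guest molecule against a BET reference area. Normalizes
    fluorescence-quench time traces, fits first-order loading/release
    kinetics, fits the concentration dependence of loading times to a
    diffusion-limited capture model and estimates the effective intraparticle
    diffusion constant. A mechanistic diffusion-immobilization simulator
    (external diffusive capture, hindered internal diffusion, Langmuir-type
    adsorption/desorption) provides a forward model and doubles as the
    seeded synthetic-data generator for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
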