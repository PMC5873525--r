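Package: passam
Title: Quantification of Passive Aerosol Sampler Deposits from Microscope
    Images
Version: 0.1.0
Authors@R:
    person("Passam", "Developers", email = "passam@example.org",
           role = c("aut", "cre"))
Description: Converts particle inventories obtained from calibrated
    microscope images of passive aerosol sampler substrates (UNC-style
    mesh-capped deposition samplers) into airborne mass concentrations
    for the PM10, PM2.5 and respirable size fractions.  Implements the
    deposition-velocity inversion under three mesh-attenuation models
    (the wind-tunnel mesh factor power law, a hybrid model capped at the
    mesh open-area ratio, and the constant area factor), the image
    segmentation and particle filtering rules used in passive-sampler
    SEM workflows (Renyi-entropy and triangle thresholding,
    connected-component sizing, edge and area exclusion), normalised
    dM/dlogda size distributions, field-blank correction, and the
    comparison statistics used to evaluate samplers against active
    reference methods (mixed-model intraclass correlation with basic
    bootstrap confidence intervals, paired squared-deviation tests,
    through-origin regression).  A synthetic module simulates lognormal
    aerosol deposition, renders micrographs and generates multi-occasion
    study tables so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
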