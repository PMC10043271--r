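Package: actopore
Title: Active-Gel Pore Dynamics and Quantification for Adherent Liposomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantifies rupture of adherent liposomes carrying a
    membrane-bound actin or actomyosin layer. Implements a reduced active-gel
    law for pore expansion (critical radius, phase diagram, pore-size dependent
    effective viscosity), a moving-boundary radial solver for the coupled actin
    density and velocity fields, hypothesis-test length scales (bendo-capillary
    and Thiele lengths, myosin thick-filament tension), trace kinetics (pore
    opening timescale, actin turnover, model fitting, group statistics), image
    quantification (radial and angular profiles, spot and blister detection,
    spot-ring width, pore radius extraction, rim tension from traction maps),
    and seeded synthetic-data generators with ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
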