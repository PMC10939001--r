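Package: surfbo
Title: Bayesian-Optimization Structure Search for Flexible Adsorbates on
    fcc(111) Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Accelerated global-minimum structure determination for flexible
    molecules (pyranose sugars) in vacuum and adsorbed on fcc(111) metal
    surfaces.  A Gaussian-process surrogate of the potential-energy surface is
    learned actively over reduced coordinates (hydroxyl and glycosidic
    torsions, ring-flip coordinates, rigid-body placements), with a
    contact-capped logarithmic energy transformation, surface-symmetry data
    augmentation, Kabsch-RMSD deduplication of harvested minima, quasi-Newton
    local relaxation, force-seeking training-data curation, and a lightweight
    descriptor-regression surrogate potential that enables a cheap second
    search pass.  Packaged idealized sugar templates, orthogonal slab
    builders, and empirical toy energy backends make the whole workflow
    runnable on a desk machine; external electronic-structure or
    machine-learned calculators plug in behind a simple calculator contract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
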