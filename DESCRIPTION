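Package: icetraj
Title: Analysis of Ice-Growth Trajectories with Small-Molecule Solutes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies ice growth in molecular trajectories of an ice
    Ih slab in contact with supercooled water and small zwitterionic
    solutes such as alpha- and beta-alanine. Provides a synthetic
    trajectory generator with ground truth, a Steinhardt bond-order ice
    classifier with seeded-cluster tracking, growth-rate and
    overgrowth/inhibition outcome classification, hydrogen-bond and
    hydration metrics, molecular volume and solvent-accessible surface
    area, ice-lattice structural-compatibility statistics, and
    well-tempered metadynamics and Bennett-acceptance-ratio free-energy
    estimators validated against analytic oracles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
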