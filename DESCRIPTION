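Package: chainscaling
Title: Polymer Scaling Exponents and Fractal Dimensionality of Protein Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the polymer scaling exponent alpha and the fractal
    dimensionality D = 1/alpha of a protein or polymer chain at any stage of
    folding from its radius of gyration, via an interpolated scaling relation
    anchored at the stretched and ideal chains. Provides Flory excluded-volume
    theory closed forms and numerical free-energy minimization, chain geometry
    on coordinates (radius of gyration, end-to-end distance, Kabsch
    superposition RMSD, RMSF, B-factor confidence classes), seeded generators
    for stretched, freely jointed, self-avoiding (pivot-algorithm) and compact
    globular chains plus alpha-scheduled synthetic folding trajectories,
    a per-frame trajectory analysis pipeline reading multi-MODEL PDB and XYZ
    files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
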