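Package: wtmetad
Title: Well-Tempered Metadynamics and Free-Energy Surface Analysis on
    Toy Ligand-Binding Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale machinery for well-tempered metadynamics studies of
    ligand binding to four-fold-symmetric receptors such as parallel
    G-quadruplex DNA. Provides analytic multi-basin free-energy landscapes
    and bead-model quadruplex/ligand structures with known ground truth,
    overdamped Langevin sampling, history-dependent Gaussian bias deposition
    with tempered heights, geometric collective variables (center-of-mass
    distance, inertia-axis torsions, projection on and distance from the
    receptor axis), reconstruction of free-energy surfaces from the bias and
    by reweighting onto unbiased collective variables, and downstream
    analysis: watershed basin detection, basin free-energy differences,
    saddle-point barriers, bound/unbound binding free energies and
    convergence profiles. Text-based COLVAR/HILLS/FES file dialects and a
    small command-line driver tie the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
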