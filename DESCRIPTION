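Package: contactmix
Title: Bayesian Classification of Molecular Conformational States from
    Binary Contact Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised identification of molecular conformational states
    from coordinate trajectories.  Frames are reduced to binary point-to-point
    contact features (e.g. alpha-carbon contact maps), which are modelled as a
    Bernoulli mixture with an unknown number of categories.  A
    Bhattacharyya-coefficient uniqueness prior removes redundant categories,
    and the posterior over the number of categories, mixture weights, category
    prototypes and per-frame assignments is explored by Markov chain Monte
    Carlo with recategorization, reclassification and reversible category
    split/join moves.  Includes generators for geometric benchmark
    trajectories, contact featurization from PDB/XYZ/DCD input, and
    time-order accuracy diagnostics for trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
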