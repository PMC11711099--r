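Package: enzopt
Title: Genetic-Algorithm Optimization of Enzyme Sequences with Pluggable
    Mutation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico directed-evolution toolkit for enzyme sequences.
    A genetic algorithm evolves fixed-length protein sequences under
    interchangeable mutation-proposal strategies (a masked-predictor
    plugin, a conservation-informed transition matrix derived from a
    multiple sequence alignment, and a uniform baseline matrix). Fitness
    comes from trainable models: a random-forest reaction-feasibility
    classifier and a gradient-boosted turnover-number (kcat) regressor,
    both operating on pluggable sequence/molecule embedders. The package
    also provides convergence diagnostics (first-hit distributions and
    one-dimensional Wasserstein distances to a one-step-convergence
    reference), rank-based statistics for mutant-versus-wild-type score
    shifts, and post-molecular-dynamics analytics: a time-windowed
    dihedral-angle deviation statistic, per-residue phi/psi correlation
    profiles, and random-mutation / poly-proline control-mutant
    generators. Synthetic-data generators with known ground truth make
    the whole pipeline testable without external databases or
    pretrained models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    randomForest,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'alphabet.R'
    'proteins.R'
    'mutations.R'
    'fasta.R'
    'transition.R'
    'predictors.R'
    'strategies.R'
    'ga.R'
    'embedders.R'
    'fitness.R'
    'stats.R'
    'convergence.R'
    'md.R'
    'synthetic.R'
    'config.R'
    'cli.R'
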