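Package: DisplaySelect
Title: Stochastic Simulation and Enrichment Analysis of mRNA-Display
    Affinity-Selection Campaigns
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the diversity scale of an mRNA-display
    (RaPID-style) macrocyclic peptide library shapes the outcome of iterative
    affinity selection. Provides the NNK library-scale arithmetic (theoretical
    diversity, ribosome and mRNA budgets, subset lineages), a 1:1 Langmuir
    binding-kinetics core with sensorgram simulation and fitting, a seeded
    round-by-round selection simulator (translation sampling, negative and
    kinetics-governed positive selection, PCR amplification with point
    mutation), NGS-side enrichment analysis (read counting, abundance triage,
    cross-library deduplication, Hamming single-linkage family clustering,
    population trajectories), and an extreme-value model of lognormally
    distributed dissociation rates linking library size to the best binder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), methods
Imports: stats, utils, tools, Biostrings, minpack.lm, yaml
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'DisplaySelect-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'library-model.R'
    'kinetics.R'
    'sensorgram.R'
    'selection-sim.R'
    'enrichment.R'
    'evt.R'
    'synthetic-data.R'
    'io.R'
    'cli.R'
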