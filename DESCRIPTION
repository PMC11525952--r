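Package: oligoconf
Title: Conformational Search and Spectroscopic Assignment for Protonated
    Peptide Oligomers
Version: 0.1.0
Authors@R: person("Oligoconf", "Developers", role = c("aut", "cre"),
    email = "maintainers@oligoconf.dev")
Description: Toolkit for gas-phase structural analysis of protonated peptide
    oligomers such as diphenylalanine complexes. Builds oligomer topologies
    with explicit protonation states (charge-solvated and zwitterionic),
    searches conformational space with a reinforcement-learning (PPO) torsion
    policy, removes duplicates with the torsion fingerprint deviation metric,
    clusters optimized conformers into interaction-fingerprint families,
    predicts harmonic IR spectra with region-wise frequency scaling and
    matches them against experimental traces, performs rigid-rotor
    harmonic-oscillator thermochemistry including free-energy crossover
    analysis between conformers, and assigns electrospray mass spectra of
    oligomer series via isotope-envelope computation and non-negative
    mixture decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
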