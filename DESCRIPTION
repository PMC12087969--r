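Package: deepniche
Title: Deep-Time Niche Dynamics, Historical Biogeography and Dispersal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable re-implementation of a deep-time
    niche-dynamics and dispersal analysis for a clade with fossil and extant
    members (modelled on the beaded lacewings, Berothidae). Provides a
    synthetic-scenario generator (fossilized birth-death trees, Brownian
    niche traits, cooling climate grids, planted wing-length/dispersal
    coupling), linear-feature maximum-entropy niche modelling with
    cross-era projection, Outlying Mean Index niche position and breadth
    through time, phylogenetic comparative statistics (Pagel's lambda,
    Blomberg's K, ancestral-state reconstruction, a nine-model evolutionary
    suite, PGLS), convergent cross-mapping causal inference,
    time-stratified dispersal-extinction-cladogenesis likelihoods with
    biogeographic stochastic mapping and dispersal-event counting, a
    dispersal-regime hidden Markov model with logistic threshold
    extraction, humid-air density and Sutherland viscosity computations,
    and habitability/accessibility map projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
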