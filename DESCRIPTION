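Package: planksucc
Title: System-Level Indices of Seasonal Plankton Succession in Quantitative Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the full family of system-level succession indices for
    mass-balanced food-web flow networks: biomass-based indices (Shannon
    functional diversity, succession rate, eco-exergy), size- and flow-based
    trophic structure (flow-weighted trophic positions, biomass and production
    pyramids, trophic transfer efficiency, predator-prey body mass ratios,
    normalized biomass size spectra, metabolic activity, system residence
    times, diet composition and stoichiometry), information-theoretic flow
    indices (flow diversity, average mutual information, ascendency,
    development capacity, weighted connectance) and weighted small-world
    metrics (characteristic path length, clustering). Ships the Lake
    Constance pelagic food-web topology (24 guilds, 8 groups, detritus pool)
    and a seeded stochastic generator of mass-balanced seasonal carbon and
    phosphorus flow networks and guild biomass series, so the whole pipeline
    is exercisable without field data. Includes phase averaging, min-max
    normalization, a composite succession index, trend classification and
    rank correlations between index series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
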