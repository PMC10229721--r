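Package: phylofauna
Title: Plant Phylogenetic and Functional-Trait Diversity Effects on Soil Fauna
Version: 0.1.0
Authors@R: person("Analysis", "Team", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking the phylogenetic diversity and single-trait
    functional diversity of local plant communities to the abundance and
    diversity of soil fauna. Implements abundance-weighted mean pairwise and
    nearest-taxon phylogenetic distances with species-reshuffling null models
    and standardized effect sizes, Rao's quadratic entropy for single traits,
    community-weighted means, a point-centred-quarter density estimator for
    grassland surveys, soil-fauna group summaries including Simpson diversity
    and the nematode Structure Index, and an ordinary-least-squares inference
    layer with a phylogenetic-by-functional diversity interaction, variance
    inflation factors and studentized-residual outlier exclusion. A
    synthetic-study generator produces phylogenies, traits with tunable
    phylogenetic signal, assembled communities and fauna responses so the
    whole pipeline can be exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
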