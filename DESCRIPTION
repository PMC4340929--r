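Package: arborant
Title: Diversity and Spatial Null Models for Arboreal Ant Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nesting versus foraging layers of arboreal
    ant communities censused on mapped forest stems. Computes per-tree and
    whole-plot species richness, sample-based rarefaction (Mao Tau) and Chao2
    incidence estimates, derives records of species foraging but not nesting
    on a tree (F-N records), and tests whether such species nest closer in
    surrounding trees than expected under fixed-marginal (quasiswap)
    randomization of the nest incidence matrix, with permutation envelopes
    and rank tests. Includes a stem-map simulator with a distance-decay
    foraging kernel so the whole pipeline can be exercised and calibrated
    against data with known spatial structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
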