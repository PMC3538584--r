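Package: devadd
Title: Deviation from Additivity of Substitution-Rate Functions in
    Distance-Based Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for weighing the systematic bias of a non-additive
    substitution-rate (SR) function against its stochastic noise when choosing
    a distance estimator for phylogenetic reconstruction. Implements the
    Kimura two-parameter (K2P) model machinery (exact transition probabilities,
    sequence simulation along trees, pairwise transition statistics), the
    classical K2P, Jukes-Cantor, transversion-only, fixed-ratio maximum
    likelihood and LogDet distance functions, a minimax measure of deviation
    from additivity with its interpolation-error bound, first-order
    (delta-method) standard deviations of the distance estimators, a
    Fisher-criterion predictor of quartet resolution accuracy with its
    separation/noise decomposition, the four-point method, neighbor joining,
    Robinson-Foulds evaluation, and reproducible simulation drivers for
    quartet and caterpillar-tree experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
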