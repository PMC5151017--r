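Package: dbnmorph
Title: Deep Belief Network Analysis of Brain Morphometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control analysis of region-wise brain morphometry
    (FreeSurfer-style cortical thickness and subcortical volumes) with deep
    belief networks. Provides parsers for aseg/aparc statistics tables,
    confound residualization and z-scoring, Bernoulli and Gaussian-visible
    restricted Boltzmann machines trained by one-step contrastive divergence,
    greedy layer-wise pretraining with supervised fine-tuning (Nesterov
    momentum combined with RMSProp), nested repeated cross-validation with a
    mixed Tree-of-Parzen-Estimators/annealing/random hyperparameter search, a
    linear support-vector-machine baseline, class-conditional Gibbs sampling
    to rank discriminative brain regions, evaluation of an intermediate
    first-episode-psychosis cohort, and a synthetic cohort generator with
    planted effects for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
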