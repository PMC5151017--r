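---
title: "Deep belief networks for brain morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep belief networks for brain morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbnmorph)
```

# Overview

`dbnmorph` implements a complete case-control analysis of region-wise brain
morphometry with deep belief networks (DBNs): parsing FreeSurfer-style
statistics tables, confound correction, generative pretraining plus
discriminative fine-tuning of a deep classifier, nested cross-validated model
selection, a class-conditional sampling probe that ranks discriminative brain
regions, and the evaluation of an intermediate (first-episode psychosis)
cohort. Because clinical MRI datasets of this kind are typically not
shareable, the package ships a synthetic cohort generator with known ground
truth, so that every stage of the pipeline is testable end to end.

# Data model

The pipeline's universal currency is a subject-by-feature table
(`morph_table`): 68 cortical thickness features (34 Desikan-Killiany regions
per hemisphere, in mm) followed by 45 subcortical/segmentation volumes (in
mm^3^), plus diagnosis (`HC`, `SCZ`, `FEP`), age and sex. The feature list is
pinned to the 45-structure segmentation output of FreeSurfer 5.0 rather than
inferred from input, because later FreeSurfer versions emit different
structure sets; pinning keeps every table, model and report
column-compatible. The canonical column order (left thickness, right
thickness, volumes in segmentation row order) is a package convention — no
ordering is inherent to the data — and sex is coded 0 = female, 1 = male,
which only flips the sign of one regression coefficient.

Parsers for `aseg.stats` and aparc-style tables are column-position based,
which is the format's own convention (data rows carry no inline header);
`#` lines are ignored wherever they occur.

# Preprocessing

Each feature is independently regressed on age and sex in a single joint
ordinary-least-squares fit (`feature ~ 1 + age + sex`), and the residuals
are z-scored (n−1 denominator). By default both transforms are estimated
across **all** subjects, which reproduces the conventional procedure for
this kind of analysis; `fit_rows` can be restricted to training folds for a
leakage-free variant, and the package's tests verify that in that mode the
fitted transforms are bit-identical under arbitrary perturbation of held-out
rows. Note that the cross-validated classifier evaluation itself never lets
test data influence training: hyperparameter search sees only training and
validation subjects.

# The deep model

**Restricted Boltzmann machines.** The first layer is a Gaussian-visible RBM
with fixed unit conditional variance — the standard choice for z-scored
inputs — and all higher layers are Bernoulli RBMs. Training is one-step
contrastive divergence (CD-1): weights are initialized from
`Normal(0, 0.01^2)`, biases at zero, minibatches of 10, 10 epochs. The
negative-phase statistics use the visible conditional probabilities/means of
a sampled hidden state and the hidden probabilities of that reconstruction
(a common variance-reduction convention); pretraining uses no momentum or
weight decay. The last short minibatch is used with its gradient averaged
over its actual size, and data are reshuffled every epoch.

**Stacking and fine-tuning.** `pretrain_dbn()` trains layers greedily, each
on the deterministic activation probabilities of the frozen layer below.
`initialize_network()` copies the recognition weights into a feedforward
network with logistic hidden units and appends a 2-unit softmax layer
initialized at zero (so the untrained classifier outputs (0.5, 0.5)
everywhere). `fine_tune()` minimizes cross-entropy plus an L2 penalty of
5×10^−5^ on the weights (not biases) for 200 epochs of minibatch-10 SGD,
with Nesterov momentum combined with RMSProp per-parameter scaling. Only the
maximum momentum (0.9) is a published constant; the schedule — linear ramp
from 0.5 over the first 10% of epochs, then constant — is the conventional
companion of Nesterov momentum in this literature, and the RMSProp constants
(decay 0.9, epsilon 10^−6^) are the usual defaults; all are configurable.
Ties in `predict_label()` go to `HC`. No dropout or early stopping is used.

**Numerics and determinism.** The training loops are compiled
(Rcpp/RcppArmadillo), but every random draw — weight initialization, epoch
shuffles, hidden-sampling uniforms — is generated on the R side from the
configured seed and passed in. A plain-R reference engine consumes the same
draws, and the test suite asserts that both engines return bit-identical
parameters; every stochastic operation is reproducible given its seed.

**Exact oracles.** For small Bernoulli RBMs (≤ 20 units) the package
computes the exact average log-likelihood by free-energy marginalization and
the exact likelihood gradient in expected-statistics form
(`exact_log_likelihood()`, `rbm_exact_gradient()`). The tests compare these
against a second, independent enumeration of the (v, h) joint and against
central finite differences, and verify that CD-1 training increases the
exact likelihood on data sampled exactly from known tiny models.

# Model selection and evaluation

Evaluation follows a nested, repeated cross-validation: 3 folds, repeated 5
times with fresh shuffles. Folds are stratified by class (plain shuffling is
available, but stratification avoids degenerate folds at cohort sizes of a
few hundred). The held-out fold is split into a validation half, which
drives hyperparameter search, and a test half touched only once by the final
model; the two halves differ by at most one subject and are class-balanced
where counts allow.

The search space is: units per hidden layer, quantized-uniform on
[10, 200]; pretraining and fine-tuning learning rates, uniform on
[10^−4^, 10^−1^]; hidden-layer count fixed per sweep (1–5,
`sweep_layers()`). Each iteration of `optimize_hyperparameters()` draws its
proposal strategy from a fixed mixture — 70% a Tree-of-Parzen-Estimators
style proposal (per-dimension Gaussian kernel density ratio between the top
quartile and the remaining trials, best of 20 candidates), 20% an
annealing-style Gaussian perturbation of the incumbent with shrinking scale,
10% uniform random — falling back to random until 10 trials exist. The
Parzen proposal is a deliberately simple reference implementation; its
fidelity target is "better than random search on smooth objectives", which
the test suite checks on a synthetic quadratic objective, not equivalence
with any external optimizer. The default budget of 50 iterations per fold
is a desk-scale choice; the full-scale design (2000 iterations per fold) is
available via `n_iter`.

Performance indicators are computed from confusion counts with SCZ as the
positive class: sensitivity, specificity, balanced accuracy (their mean) and
error rate, plus AUC-ROC implemented as the normalized Mann–Whitney
statistic (ties count one half; the tests compare it against brute-force
pairwise enumeration). A rate whose denominator is zero is reported as
undefined (`NA`), never as zero.

The linear baseline is a soft-margin linear SVM (libsvm via `e1071`), its C
chosen from {0.001, 0.1, 1, 10, 100, 1000} by validation AUC with ties
resolved to the conventional default C = 1. On near-separable training sets
the whole grid ties and C = 1 is always selected. A known limitation worth
stating: at weaker effect sizes the heavily regularized C = 0.001 model can
*rank* best (highest validation AUC) while its default decision threshold
collapses to the majority class under class imbalance, so its balanced
accuracy can sit near chance even though its AUC is high. The package
reports both metrics so this situation is visible.

An external cohort (`evaluate_external_cohort()`) is scored by the fraction
of its subjects the per-fold final models label SCZ, reported together with
the complementary HC fraction (mean ± sd over models), since either framing
("error rate" vs "classified as SCZ") may be wanted.

# The generative probe

A DBN is a generative model, so one can ask it what each diagnosis "looks
like". `train_associative_top()` attaches a top-level Bernoulli RBM whose
visible layer concatenates the top hidden activations with a one-hot
diagnosis code. `sample_class()` clamps the two label units and runs
alternating Gibbs sampling (1000 iterations by default);
`down_pass()` propagates the final top-level state deterministically through
the generative connections — Bernoulli probabilities at each layer, Gaussian
means at the bottom — yielding an input-space vector in z-score units.
`class_difference()` averages the down-passed chains per class and ranks all
113 features by the absolute prototype difference; differences can be mapped
back to mm/mm^3^ with `report_native_units()`.

Design choices taken where the procedure was genuinely open:

* **Chains.** A single chain per class is the literal minimal procedure, but
  its output is dominated by seed noise; the default averages 100
  independent chains (`n_chains = 1` restores the literal variant). The
  package's own acceptance workflow uses 500 chains for a stable ranking.
* **Initialization.** Chains start from the clamped conditional of a random
  Bernoulli(0.5) free visible state.
* **Which model is probed.** The probe uses the generative (pretrained)
  weights; fine-tuned recognition weights are not written back. Probing is
  done on a shallow stack (one hidden layer of 50 units) with the
  associative top trained longer than a DBN layer (400 epochs, learning rate
  0.1). The reasons are empirical and are worth recording: each additional
  unsupervised stacking layer attenuates the class-related *mean* shift in
  the hidden activations (the signal survives in pattern form, but the
  clamped sampler transmits mean structure), and a top RBM trained for only
  a handful of epochs couples the label units too weakly to steer the chain.
  With the shallow probe the package's tests recover planted effects
  reliably and degrade gracefully to chance as the planted effect size goes
  to zero, and label-shuffled data stay inside a permutation null.
* **Clamped-sampler correctness** is the module's load-bearing oracle: on
  tiny associative RBMs the empirical clamped conditional means over 20,000
  chains are checked against exact enumeration.

Separately, CD-1 on wide Gaussian-visible RBMs diverges at the upper end of
the learning-rate range (a known instability); diverged candidates simply
score poorly on validation AUC and are discarded by the search.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes:
group sizes 83 HC / 143 SCZ / 32 FEP; ages 35.49 ± 11.08, 37.12 ± 10.99 and
27.09 ± 7.97 years; male fractions 56/83, 95/143 and 15/32 — the demographics
of a typical chronic-schizophrenia case-control study with an intermediate
first-episode cohort, so confounding behaves realistically. Each feature is

```
mu_j + beta_age_j (age - mean age) + beta_sex_j sex + delta_j g + eps
```

with `g` = 0 (HC), 1 (SCZ) or `fep_scale` (FEP, default 0.5: morphology
midway between the other groups), and `delta_j` equal to `effect_size_d`
residual standard deviations on the ten default effect regions (a mix of
subcortical volumes and frontal/temporal/parietal/insular thickness
measures) and zero elsewhere. Residual noise is Gaussian with an
equicorrelation of 0.2 across features (a shared per-subject factor), a
minimal stand-in for the strong shared variance of real morphometry; the
default per-feature scales put thickness near 2.2–2.8 ± 0.15 mm and volumes
log-spaced over 300 mm^3^–60 cm^3^ ± 10%, so back-transformed reports are
plausible. Age slopes (−0.02 sd/year) and a male offset (+0.3 sd) are mild
atrophy/size effects. The default effect size d = 1.0 is a conventional
"large" effect chosen for testability, not a biological claim; the
end-to-end acceptance workflow uses d = 1.5, the regime in which both the
classifier and the probe should succeed clearly, and the permuted-label null
checks the other end.

What the generator does **not** emulate: scanner/site effects, segmentation
error, non-Gaussian tails, and realistic region-by-region covariance.
Passing tests therefore demonstrate correctness of the pipeline's machinery
and its statistical behavior under the assumed model, not clinical
performance on real MRI data.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the full design at desk
scale: the 258-subject default cohort, 5× 3-fold nested cross-validation,
50 search iterations per fold, and a single hidden layer for the
cross-validated classifier. The single-layer choice is deliberate: on
region-wise morphometry, depth sweeps of this design find single-layer
networks essentially on par with the best deeper stacks, and one layer
keeps the 750-training nested evaluation comfortably fast;
`search_space(n_hidden_layers = k)` and `sweep_layers()` expose the deeper
variants. Degenerate inputs fail loudly: constant features at z-scoring,
single-class training labels, non-finite data, schema mismatches, unknown
diagnosis labels, empty minibatches and cohorts. Softmax probabilities are
computed with max-subtraction; log-likelihood terms are floored at 1e-300;
`softplus` uses the overflow-safe form.

# Known limitations

* CD-1 is a biased estimator of the likelihood gradient; the label-marginal
  calibration of the associative top is approximate and needs a
  well-trained top RBM and long burn-in to sit within Monte-Carlo error of
  the data frequencies.
* The Parzen-style proposal is one-dimensional per parameter (no
  interactions) and is meant as a reference implementation.
* The probe reports associations the generative model encodes; it is not a
  causal or significance statement, and no multiple-comparison control is
  applied to the ranking.
* With `fit_rows` at its default (all subjects), preprocessing statistics
  see the test folds; this reproduces the conventional procedure and can be
  switched off.
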