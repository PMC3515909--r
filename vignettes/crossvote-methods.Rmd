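---
title: "Cross-study voting classifiers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study voting classifiers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crossvote)
```

crossvote compares seven binary classifiers and a majority-voting
meta-classifier for predicting metastasis outcome from gene-expression
matrices, across studies and across array platforms. This vignette is the
package's own account of the statistical machinery, the tunable
parameters, and the design decisions that were genuinely open.

## The pipeline

Given a collection of studies (genes × samples log-expression matrices
with a 0/1 metastasis label per sample and a platform tag), the pipeline
runs in five stages.

**1. Cross-study rank feature selection.** Within each non-test study,
every gene is scored by its signal-to-noise ratio
$S_g = (\bar{x}_{g,1} - \bar{x}_{g,0}) / (s_{g,1} + s_{g,0})$, with sample
(n−1) standard deviations and the denominator floored at $10^{-8}$ to
guard degenerate genes. Genes are ranked (rank 1 = most positive, i.e.
most metastasis-up) and ranks are normalized to $r/(n_g + 1) \in (0,1)$
so that platforms with different gene counts are comparable. Each gene's
normalized ranks are averaged over the studies containing it, and a mean
rank significantly above or below 0.5 (two-sided) flags the gene. The
null is built by permuting outcome labels independently within each
study and re-ranking everything; p-values get the plus-one correction,
or are exact fractions when the label assignments can be enumerated
(the product over studies of $\binom{n}{n_1}$ at most `exact_limit`).
Benjamini–Hochberg q-values at FDR ≤ 0.05 define the selection, which is
then intersected with the genes present in all training and test studies
(`intersect_pool()`).

Which test the original rank meta-analysis used is not restated in the
source we implement; the within-study permutation null with BH control
is our assumption-light stand-in, and is flagged as such. Similarly,
whether the signal-to-noise ratio uses population or sample standard
deviations is unstated; we chose sample SDs.

Permutation resolution bounds attainable significance: with $P$
permutations no p-value can fall below $1/(P+1)$, so the smallest
achievable q-value for the $k$-th ranked gene is roughly
$m/(k(P+1))$ for an $m$-gene universe. Selecting a 50-gene signature
from 2000 genes at FDR 0.05 therefore needs on the order of 1000
permutations; the default is 1000.

**2. Standardization and gene matching.** Every retained study is
restricted to the common selected pool (duplicate probes collapse to the
highest-variance row — common microarray practice) and each gene is
standardized to mean 0, SD 1 *within its own study*; constant genes map
to zero rows. Test sets use their own means and SDs, never the training
set's, mirroring a protocol in which all datasets are standardized up
front. Whether standardization should be per gene or per array was an
open choice; per gene is the reading under which gene-wise classifiers
transfer meaningfully across studies, and is the one implemented.

**3. Importance-ranked forward model building.** Within a training
study, the pool is ordered by random-forest permutation importance (the
standardized out-of-bag accuracy drop under label permutation). Each of
the seven methods — RF, logistic regression, four SVM kernels, and a
single-hidden-layer neural network, fitted with ranger, glm, e1071 and
nnet (ranger rather than the classic randomForest implementation: with a
fixed seed and one thread its fits are bit-reproducible, which the
package's end-to-end determinism guarantee requires) — then grows models by adding one feature at a time from
the top of that ranking, jointly grid-searching its hyperparameters.
Every candidate (prefix length k, grid point) is scored by ten-times
repeated stratified 10-fold cross-validation, pooling all out-of-fold
predictions into a balanced accuracy (bAcc, the mean of sensitivity and
specificity). The argmax wins; exact ties prefer the more balanced
sensitivity/specificity, then fewer features, then the earlier grid row
— all deterministic. The winner is refit on the full training study.

Hyperparameter grids follow the published settings: RF trees
{2000, 3000, 4000, 5000}; SVM cost {0.01, 0.1, 1, 10} and gamma
{0.001, 0.01, 0.1, 1}; polynomial degree {2, 3, 4}. Three points needed
interpretation:

* The printed mtry settings ("1, 0.5·(number of features),
  1·(number of features), 2·(number of features), total number of
  features") are degenerate read literally (2p > p). We read them as
  multiples of $\sqrt{p}$ — {1, 0.5√p, √p, 2√p, p} — clipped to [1, p]
  and deduplicated, √p being the canonical RF default.
* A linear kernel has no gamma, so L-SVM searches cost only.
* The polynomial kernel uses `coef0 = 1` (the inhomogeneous kernel).
  libsvm's default `coef0 = 0` makes an even-degree kernel blind to the
  sign of a linear class shift — structurally unable to represent the
  dominant signal here — and no coef0 setting is published.
* The network architecture is unspecified beyond "single hidden layer";
  we grid hidden units {1, 3, 5} and weight decay {0, 0.01, 0.1} with
  sigmoid activations. Logistic regression has no grid; separation on
  wide expression data is handled by the iteration cap.

Two leakage modes are provided. `mode = "prerank"` ranks features on the
full training study before cross-validation — the protocol we re-enact,
whose internal estimates are knowingly optimistic. `mode = "nested"`
re-ranks inside every CV training fold; its CV accuracy is lower on
signal-bearing data, and the package tests assert exactly that
direction. Whether feature-count selection and hyperparameter search
were nested or joint originally is not fully specified; we implement
the joint argmax.

**4. Two-level majority voting.** Internally, 10×10 CV gives each
sample ten votes per method, ordered by repetition index; the majority
of the *first nine* votes (odd, hence never tied) is the method's
consolidated label, and the majority over the seven methods' labels is
the voting classification. The vote order is our convention — the
nine-first rule presupposes an order it does not define — and is fixed
and reproducible given the seed block. Externally each method casts one
vote and the seven-way majority decides. Voting is on hard labels only.

**5. Evaluation and classifier comparison.** Performance is always
bAcc, which is insensitive to the ~1:2 to 1:3 class imbalance of
metastasis cohorts. Two classifiers are compared on an imbalanced test
set by the repeated downsampled binomial test: (1) downsample the
majority class to a balanced subset; (2) count discordant samples
(correct under A only, `a_only`, and under B only, `b_only`);
(3) Pearson χ² with 1 df of the two counts against an even split —
a McNemar-style test, no continuity correction; m = 0 gives p = 1;
(4) store p; repeat 1000 times; (5) report the median p (for an even
count, the mean of the central order statistics). "Binomial χ² test" is
ambiguous between this and the exact binomial; both are implemented and
χ² is the default to match the name. Internal comparisons use each
method's consolidated nine-vote label per sample.

## The synthetic multi-study generator

No cohort data ships with the package; `simulate_multistudy()` generates
the study collections every experiment runs on. Per gene, baseline
expression is $N(0, \sigma)$; a planted signature of `n_planted` genes
(always inside the cross-platform shared gene set, so gene matching can
retain them) gains `effect_size`·σ in metastasis samples. Class counts
are fixed by rounding — one nuisance source of test flakiness removed.
Platforms measure a shared core plus platform-specific genes, and can
distort each gene by a fixed affine map $a_g x + b_g$
($a_g$ log-normal, $b_g$ normal), drawn once per platform.

Two heterogeneity knobs extend this base model, both off by default:

* `study_effect_sd` scales each planted gene's effect per study by
  $N(1, \cdot)$ factors (truncated at zero), keeping the expected effect
  while letting cohorts differ in which genes carry it.
* `signal_penetrance` activates each signature gene per metastasis
  sample with probability π, mimicking molecular subgroups: tumours
  carry only part of the signature, and the per-gene mean class
  difference becomes π·effect.

The penetrance knob matters for a structural reason. With a single
homogeneous linear signal, all seven methods approximate the same
decision boundary and their errors are almost perfectly correlated, so
majority voting can only track the median committee member — the
empirical voting advantage then hovers at zero. Partial penetrance makes
different model families err on different tumours, which is precisely
the regime in which a majority vote beats the average committee member.
This mirrors the biological interpretation that voting averages out
subtype-driven heterogeneity.

What the generator does *not* emulate: probe-level noise, two-channel
dye chemistry, survival endpoints, or calibrated Agilent/Affymetrix
distortion magnitudes. Passing tests demonstrate correctness of the
machinery and qualitative reproduction of the cross-study phenomena
under this generative model, not performance claims about real cohorts.

## The three experiments

`run_internal()` re-enacts the within-dataset comparison: per training
study, rank → forward-select each method → consolidated CV labels →
per-method and voting bAcc, averaged over the training studies, plus all
28 pairwise downsampled comparisons on the pooled predictions.
`run_external()` trains the committee on one training study and
transfers the entire fitted classifiers to independent test studies,
reporting the mean over test cohorts.

The cross-platform regime (`same_platform = FALSE`) deserves its own
paragraph. A per-gene affine distortion applied to raw expression is
*exactly* removed by per-gene standardization — an algebraic identity
the test suite verifies. Distorting raw training data therefore cannot
degrade a standardized pipeline, yet cross-platform transfer plainly
degrades in practice: normalization is not sufficient to align
platforms. The package models exactly that residual mismatch: the
distortion is injected into the *standardized* training study (via
`apply_platform_effect()`), and the data are deliberately not
re-standardized afterwards. With both distortion SDs zero the
cross-platform run is bit-identical to the same-platform run, which the
tests assert. Both regimes train on the same training study, so the
injected distortion is the only difference between them. A test-side
variant (distorting the test cohorts instead) was evaluated and
discarded: it interacts badly with near-degenerate committee members,
whose predictions distortion can accidentally improve.

`demo_experiment_config()` freezes the desk-scale re-enactment
conditions: 7 studies (3 feature definers, 2 training studies of 60
samples, 2 test cohorts of 250 — cohort sizes in the field span roughly
50–300, with test cohorts among the largest), 150 genes per platform
with 70% shared, a 25-gene signature at effect 1.25, 30% metastasis
fraction, reduced one-to-four-point hyperparameter grids, models of at
most 4 features, 250 permutations, and distortion scale SD 0.3 / shift
SD 4 on the standardized scale. The shift dominates the scale on
purpose: a large multiplicative spread *attenuates* the effective
threshold shift b/a for tree-based models and destabilizes model
selection for kernel methods, whereas a dominant shift puts every method
into the regime where cross-platform performance collapses towards
chance — the qualitative regime reported for real Agilent-to-Affymetrix
transfer. The `"uniform"` variant (penetrance 1) is the cleanest setting
for isolating that distortion penalty; the default `"subtyped"` variant
(penetrance 0.6) is the setting in which the voting advantage
manifests.

```{r demo}
cfg <- demo_experiment_config(seed = 1)
prep <- prepare_pipeline(cfg)
internal <- run_internal(cfg, .prep = prep)
external <- run_external(cfg, same_platform = TRUE, .prep = prep)
glance(internal)
autoplot(external)
```

## Numerical and reproducibility choices

Ties in signal-to-noise ranking break by lexicographic gene id (radix
order, locale-independent). Constant genes standardize to zero rows.
Probabilistic classifiers threshold at 0.5; SVMs decide at the sign of
the decision function; no class weighting anywhere — balance is enforced
through the bAcc criterion instead. All randomness flows from one master
seed through named, independently re-runnable sub-seeds (simulate /
rank / cv / platform / compare); two runs of `run_experiment()` with the
same configuration write byte-identical report TSVs. Fold shuffles are
shared across all candidates of one forward selection, so candidate
scores differ only through the models.

Stratified folds are not optional: at a 30% minority fraction,
unstratified 10-fold CV loses the metastasis class from folds often
enough to break vote counting. `cv10x10()` aborts with a configuration
error if a training fold ever loses a class despite stratification.

## Known limitations

Internal CV estimates under `mode = "prerank"` inherit the documented
selection leakage and should be read comparatively, not absolutely. The
permutation-null feature selection is a stand-in for an unspecified
original test. Balanced accuracy on small test cohorts is noisy at the
±0.02–0.05 level, which bounds how sharply two committees can be
distinguished on a single simulated seed; the package's own acceptance
checks therefore aggregate directional claims over ten seeds. Runtimes
scale linearly in permutations, grid points, prefix lengths and CV
repeats; the demo configuration runs each experiment in about a minute,
while the full published grids at `max_features = 40` are
cluster-scale settings.
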