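---
title: "Minimalist ensembles for protein subcellular localization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimalist ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minens)
```

## The problem

Dozens of standalone tools predict the subcellular localization of a protein
from its sequence (or from external evidence such as protein–protein
interaction networks). Ensembles of such tools outperform any single one,
but the common strategy — include every available predictor — is costly and
counterproductive: most tools rely on the same features (above all amino-acid
composition), so their predictions are heavily redundant, and their shared
mistakes can dominate a vote. `minens` implements the minimalist alternative:
quantify each tool's *unique* contribution, select the smallest complementary
subset, and combine only those tools with a trained meta-classifier.

All computation operates on a *prediction table*: one row per protein, one
categorical column per predictor, plus a true-label column for training and
evaluation. Native tool vocabularies are first mapped onto a unified scheme
(default: Cytosol, Mitochondrion, Nucleus, Secretory, Others; the secretory
class aggregates extracellular, plasma membrane, ER, Golgi, lysosomal and
vacuolar compartments). The vocabulary is configurable, so a high-resolution
scheme (e.g. a 7-class yeast scheme with ER, Vacuole, Golgi and Cell
Periphery kept separate) is expressible through the same machinery.

## Contribution scores

For protein $j$, let $v_{max}$ be the size of the largest vote block,
$v_{sec}$ the second-largest, $v_{correct}$ the number of correct votes, and
$v_{p_i}$ the number of predictors (including $i$) that agree with predictor
$i$. Each predictor falls into exactly one case — correct-minority
($\alpha$), correct-majority ($\beta$), incorrect ($\theta$) — and its
per-protein contribution is

$$\alpha_{ij}\,(2 v_{max} - v_{p_i}) \;+\; \beta_{ij}\, v_{sec} \;+\;
  \theta_{ij}\,(v_{correct} - v_{p_i} - v_{max}).$$

A correct vote shared by few others earns close to $2v_{max}-1$; a correct
vote inside the winning block earns only $v_{sec}$; an incorrect vote is
penalized more, the more predictors share it. Scores are summed over
proteins and normalized across predictors to z-scores $(CS-\mu)/\sigma$.

Conventions the formula leaves open, fixed here:

* **Tied top blocks.** Every label attaining the count $v_{max}$ belongs to
  the majority group, so a correct vote in a tied-top block takes $\beta$,
  not $\alpha$ — the minority reward is reserved for genuinely non-majority
  predictions.
* **$v_{sec}$ with a single distinct label** is 0 (no second block exists).
* **Normalization** uses the population standard deviation over predictors;
  when $\sigma = 0$ (all raw scores equal) all z-scores are 0.

Contribution scores are a diagnostic — they rank tools by unique value — but
subset selection itself goes through correlation-based feature selection,
which handles pairwise redundancy directly.

## Subset selection

Predictor outputs and true labels are categorical, so correlation is
measured by symmetric uncertainty,
$SU(X,Y) = 2\,I(X;Y)/(H(X)+H(Y))$ with entropies in bits, defined as 0 when
$H(X)+H(Y)=0$. A subset $S$ of $k$ predictors is scored by the CFS merit

$$\mathrm{Merit}(S) = \frac{k\,\overline{r_{cf}}}
  {\sqrt{k + k(k-1)\,\overline{r_{ff}}}},$$

with $\overline{r_{cf}}$ the mean predictor–class SU and
$\overline{r_{ff}}$ the mean pairwise SU within $S$. The radicand is at
least $k$, so only the empty subset needs a guard.

The *minimalist chain* starts from the full predictor set and greedily
removes, at each step, the predictor whose removal leaves the highest-merit
remainder, recording every subset down to size 1; `select_minimalist(table,
K)` returns the recorded size-$K$ subset. Ties in merit (within $10^{-12}$)
remove the predictor with the lowest standalone class correlation, then the
earliest column — a deterministic policy that favors keeping informative
predictors. Two baselines are provided: top-$K$ by individual accuracy, and
exhaustive search over all $\binom{N}{K}$ subsets scored by cross-validated
ensemble accuracy.

Two cautions about the merit formula, verified against brute-force oracles
in the test suite: a *pair* of identical predictors has exactly the merit of
the singleton ($2r/\sqrt{2+2} = r$), not less; and adding an exact duplicate
of the most informative member can *raise* a subset's merit by raising
$\overline{r_{cf}}$. Duplication is only guaranteed non-beneficial among
equally informative predictors. The greedy chain is therefore validated
against a single-removal oracle rather than against folklore claims.

When selection runs inside cross-validation it is re-fit on each training
fold (`selection = "cfs"` or `"topk"`), so test rows never influence the
subset. The default, however, evaluates a user-supplied fixed subset — the
mode matching the common practice of selecting once on a training set and
then testing.

## Ensemble schemes

Five schemes combine the selected predictors' categorical outputs
(`train_meta` / `predict_meta`):

* **Accuracy-weighted voting** — each predictor casts its training accuracy
  as weight for its predicted label.
* **LDA-weighted voting** — a Fisher discriminant with a small ridge
  ($10^{-6}$) on the pooled covariance learns one scalar weight per
  predictor from (protein, candidate-location) agreement indicators; the
  predicted location maximizes the weighted vote sum plus a location
  log-prior, with the discriminant placed on its log-likelihood-ratio scale
  so the two terms are commensurable. This is deliberately a *voting* rule:
  a predictor carries the same weight whatever label it votes, which is what
  historically distinguishes LDA-based ensembles from classifier stacking —
  an unrestricted multiclass LDA on one-hot features would be statistically
  indistinguishable from the logistic-regression scheme and would make the
  scheme comparison vacuous.
* **Naive Bayes** — categorical, Laplace add-one smoothing (`e1071`).
* **Decision tree** — CART via `rpart`, minimum leaf size 2, no complexity
  pruning, depth effectively unlimited.
* **Multinomial logistic regression** — ridge-penalized softmax regression
  (`glmnet`, default $\lambda = 10^{-3}$) on one-hot encoded predictions
  (one binary column per predictor–label pair). The weak penalty guarantees
  convergence when a predictor is near-perfect and the one-hot data are
  separable; the fit warm-starts down a decreasing $\lambda$ path because a
  single small $\lambda$ is numerically fragile.

All schemes are deterministic. Prediction ties break by label-vocabulary
order. At prediction time, labels unseen during training map to an all-zero
one-hot block (LR), a missing value handled natively (NB, tree), or simply
contribute no weight (voting).

Naive Bayes deserves a caveat: its conditional-independence assumption is
*by construction* violated in the redundant regime this package targets.
With seven strongly coupled sequence-feature tools, NB double-counts their
shared evidence and lands below LDA-weighted voting in our simulations. It
is retained because it is a standard stacking baseline, not because it is
recommended here.

## Evaluation

Overall accuracy is the fraction of proteins whose predicted unified label
matches the annotation. Per-class performance uses the Matthews correlation
coefficient under one-vs-rest binarization, with the convention that a zero
denominator factor yields MCC 0. Cross-validation is stratified by class —
with realistic class imbalance (some compartments have a few dozen
proteins), unstratified folds are unstable — seeded, and pools held-out
predictions across folds; a class with fewer members than folds falls back
to random assignment with a warning. `performance_vs_k` drives the
accuracy-versus-subset-size experiment in exhaustive (dot cloud),
minimalist (chain line) or top-$K$ mode under a shared fold assignment.

## The synthetic generator

Real component predictors cannot be rerun here, so the package ships a
generator whose output reproduces the *statistical situation* the method
addresses: redundant tool groups with correlated errors plus a few tools
with unique information. Per protein, the true location is drawn from class
priors; each feature group draws one shared latent uniform and one shared
error label; each member tool copies the group draws with probability
$\rho$ (else draws privately), and is correct iff its latent uniform falls
below its per-class recall. This comonotone coupling preserves every tool's
marginal accuracy exactly while making group members' errors coincide with
tunable strength: $\rho = 1$ with identical specs gives identical columns,
$\rho = 0$ gives conditional independence given the truth.

The `yeast_lowres` preset emulates a genome-wide yeast benchmark: 1222
proteins with class priors 498/175/234/315
(Cytosol/Mitochondrion/Nucleus/Secretory) and nine predictors — seven
sequence-feature tools coupled in one group, one homology-based tool, and
one PPI-based tool with fully independent errors. The `human` preset has
1305 proteins, priors 361/327/159/458, eight predictors and no PPI tool.
Overall accuracies per tool (0.30–0.63) follow the published range for
standalone predictors on such benchmarks.

Design choices that matter, and why:

* **One sequence-feature group, not separate composition and signal
  groups.** The sorting-signal tools also use amino-acid composition; their
  errors correlate with the composition-only tools through that shared
  feature basis. Modeling them as independent groups would make a
  3-predictor subset structurally unable to match the full ensemble,
  contradicting the redundancy regime the method exists for.
* **Shared per-class recall shape within a group.** Tools built on the same
  features succeed and fail on the same kinds of proteins, so group members
  share one per-class strength profile, scaled to each tool's overall
  accuracy (e.g. the sequence group is strongest on mitochondrial and
  secretory proteins); profiles differ *between* groups (the PPI analog is
  strongest on nuclear proteins, the homology tool on secretory ones).
  Within-group per-class diversity would smuggle complementary information
  into a group that is supposed to be redundant.
* **$\rho = 0.85$.** No quantitative inter-tool correlation is available to
  calibrate against; this value puts the preset in the strong-redundancy
  regime in which a 3-predictor minimalist ensemble performs within a
  fraction of a percentage point of the 9-predictor ensemble, the regime
  reported for real genome-wide benchmarks.
* **Class-structured confusion profiles per group** (e.g. sequence tools
  misassign cytosolic proteins mostly to the nucleus and secretory proteins
  mostly to the cytosol): errors that cluster on specific wrong labels are
  what voting schemes are vulnerable to and classifier schemes can learn
  around.

What the generator does *not* emulate: multi-location proteins, missing
predictions from coverage gaps (tools abstaining on proteins without PPI
data), heterogeneous native vocabularies (all simulated labels are already
unified), and dataset-specific biases of any real tool. Passing tests on
synthetic data therefore demonstrate the correctness and qualitative
behavior of the machinery, not benchmark accuracy on any organism.

With these defaults, across seeded replicates at $n = 1000$: the PPI analog
attains the top normalized contribution score and is selected into the
$K=3$ minimalist subset in effectively every replicate; mean 10-fold CV
accuracy orders logistic regression above LDA-weighted voting above
accuracy-weighted voting at $K = 9$; and the minimalist 3-predictor LR
ensemble sits within a fraction of a percentage point of the 9-predictor
one. These statements are exactly what the test suite computes; no figure
here reports anything the tests do not reproduce.

## Numerical and degenerate-input conventions

* Missing predictions use the sentinel label `"NA"`; rows containing it are
  excluded from contribution scoring, selection and training, keeping the
  vote-count algebra well defined.
* Labels are matched case-sensitively after whitespace trimming; the TSV
  dialect (tab-separated, UTF-8, header, no quoting) round-trips tables
  bit-exactly.
* Single-class training data are an error for LR and LDA; constant one-hot
  columns are tolerated (ridge terms absorb them).
* Entropies use base-2 logarithms with $0\log 0 = 0$; SU is clamped to
  $[0,1]$ against floating-point drift.
* Replicated experiments derive seeds as base + replicate index; every
  seeded routine restores the caller's RNG state.

## Problem sizes used by the shipped tests

The test suite exercises oracle comparisons on tables of 100–300 proteins,
recovery and scheme-ordering experiments on 20–50 replicates of 1000
proteins, and exhaustive-search dominance on a 6-predictor, 240-protein
table with 10-fold cross-validation — sizes at which every property tested
is stable, while the whole suite completes in well under a minute on one
core.

## Known limitations

* The built-in location mapping covers the published CELLO and WoLFPSORT
  translations plus the generic six-class secretory rule; other tools'
  native vocabularies must be supplied as mapping files.
* The greedy backward chain is a heuristic: it is validated to never beat
  exhaustive search and to track it closely in simulations, but offers no
  optimality guarantee.
* Contribution scores require complete prediction rows; tools with sparse
  coverage shrink the effective scoring set.
* Ensembles are species- and dataset-specific: a meta-classifier trained on
  one organism's prediction table has no validity claim on another.
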