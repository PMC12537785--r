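---
title: "Classifying adjuvants and predicting antibody titers from blood transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying adjuvants and predicting antibody titers from blood transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adjuvantnet` analyses multi-arm vaccine-adjuvant cohort studies in which
animals are bled before and after each vaccine dose and profiled by bulk
RNA expression. Three questions drive the design: can the adjuvant an
animal received be recognised from its early expression response; can the
antibody titers it will eventually mount be predicted from the day-1
response; and which genes carry that signal. This vignette documents the
models, the choices behind every tunable, what the synthetic generator
does and does not emulate, and the package's known limits.

## Data preparation

Expression arrives as FPKM (fragments per kilobase of transcript per
million mapped reads), a non-negative, heavily right-skewed unit. The
pipeline applies

\[ t = \log_{10}(\mathrm{FPKM} + c) + c, \qquad c = 0.01 . \]

The pseudo-count $c$ avoids $\log 0$; it is small enough that values in
the detectable range are essentially $\log_{10}$ FPKM. The trailing $+c$
merely shifts the scale and is kept so that the filter threshold below is
applied on exactly this shifted scale. $\log_{10}$ is used (rather than
$\log_2$ or natural log) so that up- and down-regulation are symmetric in
interpretable decades.

**Low-intensity filter.** A gene is retained iff there exists at least
one *condition* — a (group, timepoint) combination — in which **all** of
the gene's samples satisfy $t \ge -1$ (i.e. FPKM above roughly 0.1).
Filtering acts on whole genes, not individual values, so the pipeline can
report exact retained/removed gene counts at every stage and the
bookkeeping identity `n_in == n_retained + n_removed` is asserted on
every run. The "all replicates of at least one condition" form keeps
genes that are reliably expressed anywhere in the design, while a single
stray above-threshold replicate is not enough.

**Ortholog mapping.** Non-human gene identifiers are translated to human
symbols through a static two-column table; unmapped genes are dropped and
counted. When two source genes map to one symbol, the source row with the
higher mean transformed expression is kept and the collision is logged —
the alternative (summing or averaging collided rows) would mix
measurement scales of distinct transcripts.

**Panel and fold change.** Analysis is restricted to a curated
immune-gene panel (the package is agnostic about its provenance; the
synthetic generator emits one). The unit of analysis is the per-animal
baseline fold change: each day-1/day-7 sample minus the same animal's
pre-dose sample *of the same dose*. Using the matching dose's pre-dose
draw (rather than a single day-0 baseline for both doses) removes slow
drift in an animal's baseline between dose 1 and dose 2.

**Standardization.** Features are centred and scaled to unit *population*
variance (divide-by-$n$), the convention of the common machine-learning
scalers, so frozen expectations match those tools. Constant features map
to all-zero rather than dividing by zero. The scaler is always fitted on
training data only and applied to held-out data — the model-fitting
function does this internally — so cross-validation results carry no
leakage through the scaling.

## The network

The estimator is deliberately the smallest architecture that fits the
problem: input layer of panel genes, one hidden layer of 100 ReLU units,
and an output head — softmax with one node per observed class for
classification, linear with one node per (HPV type, week) target for
regression. A fully connected layer is the right inductive bias here:
gene features have no meaningful ordering, so convolutional weight
sharing over neighbouring features has nothing to exploit, and the model
should be invariant to feature permutation (it is, once columns are
aligned by name).

Training choices, all configurable and all recorded in the fitted object:

* **Optimiser**: plain mini-batch gradient descent. No momentum or
  adaptive scheme — the smallest fully reproducible choice, and the loss
  surfaces here (a few hundred instances, strong signal) do not need
  more.
* **Loss**: cross-entropy (softmax head) or mean squared error (linear
  head).
* **Defaults**: 300 epochs, learning rate 0.01, batch size 16. For the
  titer regression the cross-validation wrapper defaults to 1,500 epochs
  at learning rate 0.02: 18 simultaneous regression targets from a few
  dozen animals converge more slowly than the classification task, and
  the higher budget is still seconds of compute.
* **Initialisation**: seeded uniform on $(-1, 1)$ scaled by
  $1/\sqrt{\text{fan-in}}$; biases zero. The same seed yields
  bit-identical weights, and the seed drives the batch shuffling too.
* **No early stopping, dropout or weight decay** — regularisation is not
  needed at these signal strengths, and omitting it keeps the weight
  matrices directly interpretable by the saliency analysis.
* Regression targets are internally standardized during optimisation and
  predictions returned on the original scale; this makes one learning
  rate work across titer scales.
* A non-finite loss aborts training with a diagnostic rather than
  silently producing NaN weights.

## Cross-validation and metrics

Classification instances are the post-dose fold-change vectors — one per
(animal, dose, timepoint) — labelled by adjuvant group; an optional mode
concatenates day-1 and day-7 into one instance per (animal, dose) for
designs where the timepoints are believed to carry one joint signature.
Because some groups may be larger than others, majority groups are first
randomly undersampled to the minority size (discards are logged), then
instances are assigned to $k$ folds stratified by class. "Averaging" test
results across folds is realised as pooling the held-out predictions into
one confusion matrix: with equal-sized folds this equals the mean of
per-fold accuracies (asserted in the tests), and it remains well defined
when folds differ by one instance. Per-fold accuracies are also reported.

Per-class metrics follow the standard confusion-matrix definitions (TPR,
FNR, precision, FDR, F1). Ratios with zero denominators — a class never
predicted, say — are reported as `NaN` with a `defined` flag, never
silently coerced to 0, because a 0 there would masquerade as a terrible
score rather than an undefined one.

The random-forest arm exists purely as the conventional-baseline
comparison, run on identical folds; 500 trees, seeded. No significance
test between the two arms is attempted.

## Saliency

For a trained network, the effective weight of gene $r$ for class $s$ is

\[ W_{r,s} = \sum_q \max(0, W^{(2)}_{s,q}) \, \max(0, W^{(1)}_{q,r}) , \]

i.e. the product of the layer weights with every negative entry clamped
to zero first. The clamping is the literal reading of "the ReLU sets
negative values to zero" applied to the weights: it restricts attention
to purely excitatory paths from gene to class score. (The alternative —
propagating signed products and clamping the result — gives a different
quantity; the package implements the per-entry clamp.) Biases are
excluded. For a network whose weights happen to be non-negative and an
input with all hidden units active, $W_{r,s}$ equals the gradient of the
class-$s$ pre-softmax score with respect to gene $r$; this oracle
equivalence is verified numerically in the tests against central finite
differences.

The raw matrix is min–max normalized to $[0,1]$ globally (so columns are
comparable), clustered on correlation distance $1 - r$ with average
linkage, and genes are ranked by mean normalized weight across classes —
the "across all classes on average" reading, applied to both the top and
the bottom set. Ties are broken lexicographically by symbol so the
ranking is deterministic. Saliency is computed per cross-validation fold
model and averaged; the per-fold matrices are retained, and their mean
pairwise rank correlation is the fold-stability diagnostic.

The top-100 and bottom-100 sets are then compared *between groups*: for
each group pair and timepoint, the Pearson correlation of the two
groups' mean fold-change vectors restricted to each set, with a
two-sided p-value from the exact $t$ transform on $n-2$ degrees of
freedom ($n$ = genes in the set) and a $p < 0.05$ significance flag. The
expected structure — group-discriminative genes decorrelate groups, while
low-weight genes respond similarly everywhere — appears as bottom-set
correlations exceeding top-set correlations for most pairs.

## What the generator emulates — and what it does not

`simulate_study()` produces a cohort, an FPKM matrix and a titer table
with the statistical structure the analysis assumes:

* **Cohort**: $n$ animals randomly assigned to 8 groups, bled at
  pre-dose/day-1/day-7 around each of 2 doses (six draws per animal).
  The default allocation gives any remainder to groups 6 and 7, so the
  default cohort has the majority-class structure that makes the
  undersampling step do real work.
* **Expression**: simulated on the $\log_{10}$ scale — per-gene baseline
  $\mathcal N(1, 0.5^2)$, per-sample noise sd 0.5 — and exponentiated as
  $\mathrm{FPKM} = \max(10^z - 0.01, 0)$, so the pipeline transform
  recovers $z + 0.01$ exactly and planted effect sizes are in the same
  units as the analysed data. 20% of genes are below-detection
  everywhere (transformed value < −1) to exercise the filter; 10% of
  genes lack a human ortholog to exercise the mapping.
* **Signatures**: each group gets 40 planted genes (drawn from the
  panel) shifted by 2.0 post-dose; groups 6 and 7 share 75% of their
  planted set, emulating the two arms that share an immunostimulatory
  molecule and making them deliberately confusable. A further 100 panel
  genes carry a common post-dose shift of 1.0 in *every* group — the
  shared (alum-driven) vaccination response. This component is what
  gives the bottom-saliency genes their cross-group correlation; without
  it, uninformative genes would be pure noise and the bottom-set
  analysis would have nothing to find.
* **Titers**: for the nine HPV VLP types, week-12 titers are a fixed
  linear map of the animal's day-1 (dose-1) transformed expression of 20
  driver genes drawn from the planted pool, plus a per-animal baseline;
  week-36 adds a second-dose boost. With all noise at zero the titers
  are an exact deterministic function of day-1 expression, which is what
  makes parameter-recovery tests sharp.

Deliberately **not** emulated: negative-binomial count noise and
library-size effects (expression noise is gaussian on the log scale),
pathway-level co-regulation, covariates such as age and sex, and any
nonlinearity in the expression-to-titer map. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes, at
realistic noise levels — not that real cohort data is this clean, nor
that real titers are linear in day-1 expression. The within-group
biological variance of real data is unknown; the default noise sd of 0.5
log10 units is a free parameter chosen to be demanding but not hopeless,
not an estimate from data.

## Study conditions and problem sizes

The packaged study conditions — used by the end-to-end tests and the
acceptance script — are a scaled-down cohort chosen so the full pipeline
runs in minutes on one core: 24 animals (3 per group), 2,000 genes,
300-gene panel, 40 planted genes per group, effect 2.0, noise 0.5,
3-fold balanced cross-validation, generator seed 7. The titer-regression
assessment uses the study-scale cohort of 60 animals (groups 6/7 holding
the remainder, sizes 7,7,7,7,7,9,9,7), 20 driver genes, 5-fold
cross-validation, at two noise levels: titer noise at 10% of the titer
sd, and fully noiseless. With 8 groups × 4 post-dose samples per animal,
these give 96 classification instances and 60 regression instances.

One arithmetic consequence of the conditions is worth stating: with 40
planted genes per group the distinct planted genes far outnumber the
100-gene top saliency set, so "recovery" is measured as the planted
fraction *of* the top set (enrichment/precision), not the recovered
fraction of all planted genes, which no 100-gene set could reach.

## Numerical and degenerate-input conventions

* Softmax is computed with the row-max subtracted; probabilities sum to
  1 within 1e−12.
* Min–max normalization rejects a constant saliency matrix rather than
  returning 0/0.
* Zero-variance rows in the clustering get distance 2 (the maximum of
  $1-r$) to every other row and are logged.
* Pearson p-values use `cor.test`'s exact $t$ transform; no permutation
  approximation.
* Fold assignment, undersampling, weight initialisation and batch
  shuffling each consume a seed derived from one master seed by fixed
  offsets; `run_all()` logs them all, and two runs from the same master
  seed are byte-identical on disk.
* Model serialization is JSON with full-precision numbers; a saved and
  reloaded network predicts identically.

## Limitations

The network is a single-hidden-layer estimator trained by first-order
descent: it is not a route to state-of-the-art accuracy but to an
interpretable weight structure. Saliency considers excitatory paths
only; genes acting through double-negative paths receive no credit. The
inter-group correlation analysis treats genes within a set as
independent observations when computing $p$-values, as the underlying
test requires, which real co-expression violates. And all quantitative
guarantees in the test suite are statements about the generator's
assumptions, not about any particular real dataset.
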