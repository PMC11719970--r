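---
title: "Methods: biomarker screening and multi-class prediction from methylation beta values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker screening and multi-class prediction from methylation beta values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Illumina methylation arrays measure, at each assayed CpG site, a *beta
value*: the fraction of methylated signal, a number in $[0,1]$. Disease
processes — cancers and age-related degenerative conditions in particular —
shift the methylation level of specific CpG sites, so a matrix of beta
values (samples $\times$ probes) carries diagnostic signal. The difficulty
is scale: even the probe set shared across the 27K/450K/EPIC platforms is
four orders of magnitude larger than the handful of CpGs a clinically
usable biomarker panel can contain, and most probes carry no signal at all.

`methylscreen` implements a two-stage screening procedure plus downstream
validation machinery:

1. **Tree-ensemble screen.** A randomized-tree ensemble (bootstrap samples,
   $\sqrt{p}$ candidate probes per split, Gini impurity) is fit to the
   binary healthy/disease task. Per-probe importance is the normalized
   total impurity decrease; probes the ensemble never splits on have an
   importance of exactly 0 and are removed, the rest are ranked descending.
2. **Feature-count scan.** A multi-scale 1D convolutional network (below)
   is evaluated by stratified $k$-fold cross-validation on the top-$n$
   ranked probes for $n$ on a fixed-step grid. The selected panel size is
   the smallest $n$ whose fold-averaged Matthews correlation coefficient
   (MCC) is within a tolerance of the grid maximum — the minimum number of
   CpGs achieving near-optimal performance.
3. **Clustering.** Samples are linked to their $K$ most cosine-similar
   neighbours; Louvain modularity maximisation partitions the graph, and a
   scan over $K = 1..50$ locates the smallest $K$ at which the community
   count is stable. The same machinery is applied to raw beta values at
   the selected CpGs and to the multi-class network's embeddings.
4. **Multi-class prediction.** A residual 1D network distinguishes
   neurodegenerative disease, bone-degenerative disease, breast cancer and
   healthy samples, with stratified 5-fold cross-validated reporting and an
   untouched independent test split.
5. **Attribution.** Per-CpG, per-class Shapley values of the predicted
   class probabilities, averaged over training samples.

# Models

## Binary diagnosis network

Each sample is a length-$p$ single-channel sequence, ordered by the
stage-1 importance ranking so that a "top-$n$" panel is a contiguous
prefix. Three parallel branches process it with kernel sizes 3, 5 and 7;
each branch repeats [conv → conv → pool] (`blocks_per_branch = 2`,
filters 32 then 64 by default, max-pooling of width 2, ReLU on every
convolution). Branch outputs are flattened and concatenated, passed
through a dense ReLU layer (64 units) and a single sigmoid output, and the
model is trained with Adam on binary cross-entropy.

*Fusion choice.* With per-branch kernel sizes and valid padding the branch
outputs have different lengths, so channel-wise merging is not defined;
the branches are flattened then concatenated. Padding is configurable
(`"valid"` by default; `"same"` keeps small panels viable — a 20-CpG input
cannot feed two valid-padding blocks of kernel 7).

*Decision threshold.* Scores in $(0,1)$ are binarised at the threshold
maximising TPR $-$ FPR (Youden's $J$) over candidate thresholds placed at
midpoints between consecutive distinct scores plus below-min/above-max
sentinels. The rule is strict (`score > threshold` → 1), ties between
equally good candidates break toward the larger threshold, and the
threshold is always selected on a validation split carved out of the
training data — never on the test split. With this candidate set the
selected $J$ is never negative: the above-max sentinel (predict nothing)
always achieves $J = 0$.

## Multi-class residual network

A convolutional stem (kernel 7, 32 filters, "same" padding) and a width-2
max-pool feed three residual blocks: block 1 has two convolutions, blocks
2 and 3 have three, with channels 32/64/128 and strides (1,1), (2,1,1),
(2,1,1). Every convolution inside a block applies ReLU (following the
architecture description literally); the block output is `body(x) + skip(x)`
with no post-addition activation. Whenever the channel count or total
stride changes the shape, the skip path is a linear 1×1 strided projection
— the standard residual resolution of a shape mismatch, which the source
architecture leaves unstated. Global average pooling yields one value per
final-block channel (the 128-dimensional sample embedding used for
clustering), and a 4-unit softmax head gives class probabilities. Training
uses Adam on categorical cross-entropy; `train_multiclass()` first runs
stratified 5-fold cross-validation (a fresh seeded model per fold),
reports per-fold accuracy / macro precision / macro recall / macro F1 with
an `Avg` row, then refits on the full training split.

Both networks are implemented on a small internal engine (im2col + GEMM
convolutions in C++, Adam and orchestration in R) whose backward pass is
verified against central finite differences in the unit tests. No tree or
deep-learning framework for R is assumed by the runtime environment, which
is why the ensemble and the networks are built in-package.

## Clustering

Cosine similarity is used without feature scaling: beta values share the
$[0,1]$ scale, and the embeddings are used as-is. Directed $K$-nearest
neighbour lists are symmetrized by union (every node keeps an edge to its
nearest neighbour, as the procedure's description implies), ties broken by
(similarity descending, sample id ascending). Edges with non-positive
similarity are dropped — modularity on negative weights is ill-defined —
which removes nothing on non-negative data. Louvain itself is delegated to
`igraph::cluster_louvain()` (seeded); the modularity reported with every
partition is recomputed independently by `graph_modularity()`, and the
test suite checks this dual route against an exhaustive-enumeration
optimum on a two-clique fixture.

The $K$-stabilization scan declares the community count stable at the
smallest $K$ whose count is unchanged for the following 4 values of $K$
(the `window`). The plateau reported for the embedding analysis in the
source work spans 14 consecutive values of $K$, so any window well below
that reproduces the qualitative rule; 4 is the package default and is
configurable. If no plateau exists the scan flags itself unstable and
returns `k_max`.

## Shapley attribution

The estimator is permutation sampling: for each sampled feature ordering,
features switch one at a time from a baseline vector (training-set feature
means by default) to the sample's values, and each switch's marginal
change in every class probability is credited to the switched feature.
Estimates satisfy the additivity identity
$\sum_j \phi_j = f(x) - f(\text{baseline})$ exactly per permutation, hence
also after averaging. The attribution target is the softmax probability of
each class, giving four values per CpG. An exact coalition-enumeration
mode (`exact = TRUE`, up to 12 features) exists chiefly so tests can
compare the sampler against ground truth; the test suite checks the dummy,
symmetry and additivity axioms and convergence of the sampler.

# Evaluation conventions

* MCC $= (tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}$.
* Any metric with a zero denominator is reported as 0 and listed in a
  `degenerate` attribute, keeping reports total instead of propagating
  NaN.
* Multi-class precision/recall/F1 are macro-averaged one-vs-rest. The
  source work reports single scalars without stating the averaging; macro
  is the symmetric choice for its near-balanced four-class design.
* All cross-validation is stratified; the train/test split is stratified
  8:2 with a fixed seed; fold assignment in the feature scan is fixed
  across grid points so panel sizes are compared on identical splits.

# The synthetic cohort generator

No accessions are published for the original cohorts, so the package ships
a generator that emulates the structure the analysis assumes, and every
claim the test suite makes is a claim about this stated world:

* **Noise model.** Beta values are drawn from
  $\mathrm{Beta}(m s, (1-m) s)$ — the mean/precision parameterization
  natural for fractions — with per-probe background means uniform on
  $(0.1, 0.9)$ and concentration $s = 50$ by default (noise sd
  $\approx \sqrt{m(1-m)/(s+1)}$, about 0.05–0.07 at mid-range means, a
  realistic blood-array scale). All means are clamped to $[0.01, 0.99]$
  before sampling so the Beta parameters stay valid.
* **Planted markers.** Each disease class gets its own disjoint CpG subset
  whose mean shifts by `effect_delta`; the direction is random per probe
  (hyper- and hypo-methylation both occur) but forced toward the feasible
  direction when only one of $m \pm \delta$ stays inside the clamp,
  so planted effect sizes are not silently truncated. Healthy samples are
  the unshifted reference.
* **Subtypes.** A class with $T$ subtypes adds a secondary
  `effect_delta / 2` shift at a subtype-specific probe subset (of the same
  size as the planted-marker sets, drawn from background probes, disjoint
  within a class), mimicking classes that occupy several communities.
* **Ages.** Healthy samples draw ages from an equal-weight two-component
  normal mixture with means 33.74 and 62.38 years (sd 8 years), and 10% of
  probes drift linearly with age (per-probe slope $\sim N(0, 0.004)$ per
  year). Over the ~29-year gap between components this moves drifting
  probes by roughly one to two noise standard deviations, which is what
  makes the healthy population separate into two age communities.

What the generator deliberately does **not** model: Infinium I/II probe
chemistry, batch effects, cell-composition confounding, platform-specific
normalization, or correlated probe blocks. A green test therefore
establishes that the machinery recovers planted structure under honest
noise — not that any particular clinical performance level would be
attained on real cohorts.

One consequence worth spelling out: with age drift enabled, community
detection on raw betas correctly yields *five* communities on a four-class
cohort, because healthy splits in two by age — the same phenomenon the
original analysis reports. The class-recovery acceptance test therefore
states its world with `age_slope_sd = 0`; the age-driven split is a
feature of the generator, not a clustering failure.

# The assembled pipeline

`run_pipeline()` chains the stages on one simulated four-class cohort:
the binary screening task is derived from it as healthy-versus-any-disease
(pooling the three disease classes), the stage-1 ranking and stage-2 scan
run on the training split of that binary task, and the selected panel then
feeds the raw-beta clustering, the multi-class model (trained on the 8:2
training split, evaluated on the untouched test split), the
embedding clustering of the test split, and attribution over a seeded
subsample of training samples. Using a single cohort end-to-end means the
probes the screen selects are exactly the probes the multi-class stage
needs — the same relationship the two-stage design assumes on real data,
where the multi-class panel is the end product of the binary screen.

# Numerical and design choices

* **Exact zeros.** The zero-importance filter tests `importance != 0`
  literally; impurity importances are exactly zero for probes never split
  on, so no tolerance is involved. Ties in the ranking break by probe id.
* **Selection tolerance.** "Optimal results" is operationalized as
  MCC within `tol = 0.005` of the grid maximum; the published table this
  mirrors separates its chosen panel from the full set by 0.003 MCC, so
  the tolerance is of the same order. Both the metric and `tol` are
  configurable. `select_count` is monotone: a larger tolerance never
  selects a larger panel.
* **Seeding.** Every stage seed is derived from the global seed by a
  stable string hash of the stage name; reruns of `run_pipeline()` with
  one config are byte-identical, and the run manifest records config and
  seeds.
* **Degenerate inputs.** Readers reject ragged tables, duplicate ids,
  values outside $[0,1]$ and (in strict mode) missing values; lenient mode
  mean-imputes per probe and says so. Networks validate that the input
  width survives their pooling/stride reductions and raise sizing errors
  otherwise. An edgeless similarity graph partitions into singletons with
  a flag rather than failing.
* **KNN ties.** The deterministic tie-break (similarity descending, then
  sample id) means exactly $K$ directed neighbours per node even among
  exact ties; with identical rows and $K = 1$ the union graph is a star
  around the lowest-id node, not a triangle.
* **CLI stages.** Subcommands other than `run-all` recompute the pipeline
  from the start through the requested stage instead of resuming from
  artifacts: at synthetic scale recomputation is cheap, and it keeps every
  artifact attributable to a single seeded code path.

# Limitations

* The networks are trained by a compact in-package engine; it is exact
  (gradient-checked) but not performance-tuned for panels beyond a few
  thousand probes.
* Shapley sampling cost grows as samples × permutations × features;
  the pipeline subsamples attributed training samples (seeded,
  configurable) to stay within desk-scale budgets.
* The gene-manifest filter implements only set intersection; enrichment,
  protein-interaction and hub-gene analyses that produce curated gene
  lists are external to this package by design.
* Multi-platform merging/normalization before probe intersection is out of
  scope; only the intersection itself is provided.
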