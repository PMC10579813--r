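---
title: "Multi-label syndrome differentiation with deep forest cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label syndrome differentiation with deep forest cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A clinical record in traditional Chinese medicine pairs a set of
standardized symptom terms with one or more *syndrome* labels; syndromes
rarely occur singly, so differentiation is a multi-label classification
task. The corpora are small (hundreds of records), the feature space is
sparse and high-dimensional (hundreds of symptom terms, mostly irrelevant
to any given syndrome), and label frequencies are long-tailed — the
commonest syndrome can appear hundreds of times while many appear once.
`syndforest` implements a pipeline built for exactly this regime: a
supervised multi-label feature filter to strip uninformative symptoms,
followed by a deep forest cascade, an ensemble architecture that performs
representation learning without the sample sizes deep networks need.

Formally, records are vectorized to a design matrix $X \in \mathbb{R}^{n
\times f}$ (binary presence or TF-IDF weights of $f$ symptom terms) and a
binary label matrix $Y \in \{0,1\}^{n \times m}$ over $m$ syndromes.

## Preprocessing

`clean_records()` drops records lacking symptoms or labels and merges
records with identical symptom sets into one record whose label set is the
union — the step that converts separately-recorded single-syndrome cases of
one presentation into genuinely multi-label records. The merge key is the
standardized symptom set: patient identity is not part of the data model,
and identical presentations are the only safe equivalence. The operation is
idempotent.

`standardize_records()` maps variant spellings to standard terms through a
user-supplied dictionary (in practice derived from a symptom-term
database). Mapping is applied exactly once; a dictionary with chained
entries (`a -> b`, `b -> c`) violates the idempotence invariant and is
flagged with a warning rather than chased, so the result never depends on
iteration order.

TF-IDF uses presence (not multiplicity) as term frequency — symptoms are
findings, not tokens — with the smoothed inverse document frequency
$\mathrm{idf}(p) = \ln\!\frac{1+n}{1+\mathrm{df}(p)} + 1$ and per-record
L2 normalization, so ubiquitous symptoms keep a small positive weight
rather than dividing by zero.

## The feature filter

`ml_relieff()` is a multi-label ReliefF: a feature is informative when
records with the same label set take similar values on it and records with
different labels take dissimilar values. Every record is visited once as a
probe (*traversal*, not random sampling — with long-tailed label sets,
random probes systematically miss rare presentations). For probe $t$, the
*hit* neighborhood holds the $K$ most similar records whose label set
equals the probe's exactly, and for every syndrome $C$ outside the probe's
label set, the *miss* neighborhood $Miss_C$ holds the $K$ most similar
records carrying $C$. The weight update per feature $p$ subtracts the
similarity-weighted mean range-scaled difference to hits and adds the
prior-weighted analogue over every miss class:

$$W_p \leftarrow W_p
 - \frac{\sum_j \mathrm{sim}(t, Hit_j)\, d(p, x_t, Hit_j)}
        {n \sum_j \mathrm{sim}(t, Hit_j)}
 + \sum_{C \notin LS_t} \frac{P(C)}{1 - P(C_{x_t})} \cdot
   \frac{\sum_j \mathrm{sim}(t, Miss_{Cj})\, d(p, x_t, Miss_{Cj})}
        {n \sum_j \mathrm{sim}(t, Miss_{Cj})}$$

Sample similarity is the reciprocal of the Pearson distance,
$\mathrm{sim} = 1/(1 - \rho)$. Unlike the cosine similarity used by the
original multi-label ReliefF (available here as `similarity = "cosine"`
for ablations), the Pearson form centers the vectors first, so it responds
to magnitude as well as direction.

Decisions the formulation leaves open, and how this package resolves them:

* **$K$** is not prescribed; the default is 10, the conventional ReliefF
  neighborhood, exposed in every API.
* **The $\rho \to 1$ singularity.** Duplicate-direction records are common
  in sparse binary data, so $\rho$ is clamped at $1 - \varepsilon$
  (default $\varepsilon = 10^{-6}$, similarity cap $1/\varepsilon$). A
  zero-variance record cannot produce a correlation at all and contributes
  the floor value $\varepsilon$ instead of an error.
* **$P(C_{x_t})$ for a multi-label probe** is taken as the mean prior of
  the probe's labels, clamped below $1 - 10^{-12}$; for single-label
  probes this reduces exactly to the classic ReliefF prior ratio.
* **"Same class"** means exact label-set equality for hits; $Miss_C$
  membership requires only that the record carries $C$. A probe with a
  unique label set simply has no hit term, and an empty $Miss_C$
  contributes nothing (its normalizer would be zero).
* **Neighbor ties.** Similarities are quantized to 12 significant digits
  before ranking and exact ties break toward the lower record index. In
  low-dimensional or duplicated records the correlation is exactly $\pm 1$
  and mathematically tied similarities are the rule, not the exception;
  without the quantization the neighbor sets would depend on the
  floating-point path used to compute the correlation. Weight terms use
  the full-precision similarities.
* The per-term normalizer keeps the printed form $n \sum \mathrm{sim}$
  even when fewer than $K$ neighbors exist (no renormalization by the
  realized count).

`select_features()` keeps the top-$n$ features by descending weight (ties
toward the lower index); the CLI default of $\lceil f/4 \rceil$ is a
pragmatic artifact-level choice, always user-overridable.

## The cascade

`cascade_fit()` grows layers; each layer holds **two multi-label forest
groups** of 40 trees each: a predictive-clustering forest (`rfpct`, splits
maximize total label-variance reduction) and a per-label-Gini forest
(`mlrf`). For binary label matrices the two criteria are mathematically
proportional ($\sum_l p_l(1-p_l)$ up to a constant), so the groups differ
through their randomization streams rather than split geometry; both code
paths are kept because the criteria diverge for non-binary targets and the
two-group structure is part of the architecture. Leaves store mean label
vectors and a forest's score is the per-tree average. Trees bootstrap and
subsample $\sqrt{f}$ features per split; split ties break toward the
lowest feature index, then the lowest threshold, and an impure node with
no impurity-reducing split (XOR-like label structure) is force-partitioned
so deeper splits can resolve it. Tree induction is implemented in C++ with
a package-private RNG, making fits bitwise-reproducible per seed.

Each layer's output representation $H$ ($n \times 2m$) is built from
**out-of-fold predictions** under internal 5-fold cross-fitting, the deep
forest convention that prevents a layer from memorizing its own training
rows; the per-fold forests are retained and averaged at prediction time.
The **measure-aware feature reuse** rule turns $H$ into the carried
representation $G$: per record, the confidence of $H$'s row — the mean
over labels of $\max(s, 1-s)$ on the averaged score block — is compared
with a threshold fixed at the 30th percentile of first-layer confidences;
low-confidence rows keep their previous $G$. The cited architecture names
this mechanism but not its formula; this concrete proxy is a documented
stand-in, chosen because it is testable row-by-row.

**Measure-aware layer growth**: after each layer the tracked measure
(default average precision; any of the six ranking/label measures) is
evaluated on the out-of-fold scores, and growth exits once the best value
has not improved for three consecutive layers (strict improvement beyond
$10^{-6}$ — "no update" is read as no strict improvement) or at
`max_layers` (default 20). The selected depth is the best layer in the
history, so the tracked measure at `best_depth` is optimal by
construction. Prediction propagates representations through layers
$1..\mathrm{best\_depth}$, thresholds scores at 0.5 (the cut is
configurable; no canonical value exists for it), and promotes the
top-scoring label on any all-zero row — every case carries at least one
syndrome by the task's definition.

## Evaluation measures

`evaluate_all()` reports eleven measures. Six use confidence scores:
hamming loss, one-error, coverage, ranking loss, average precision, and
macro-AUC. Five compare label *sets*: `mlACC` (Jaccard), `mlPRE`, `mlREC`,
`mlF1`, and exact-match `ACC`. Conventions worth knowing:

* **Coverage** is normalized by $1/(nm)$ — the form printed in this
  method family's tables — not the textbook $1/n$; `conventional = TRUE`
  gives the latter for cross-library comparison.
* **Ties.** Ranking loss and macro-AUC count score ties fully against the
  model (the printed $\le$ convention); `ties = "half"` gives the
  half-credit form used by most libraries. Rank ties elsewhere break
  toward the lower label index, uniformly across one-error, coverage and
  average precision, so all measures are deterministic.
* **mlF1** is the harmonic mean of the *aggregate* precision and recall,
  not the instance-wise mean.
* An empty predicted set contributes 0 to `mlPRE`; rows without negative
  labels are skipped by ranking loss with a warning; single-class labels
  are excluded from macro-AUC with a warning.

## The synthetic generator

`synth_generate()` produces corpora with known ground truth: Zipf label
marginals (long tail), pairwise label correlation through a comonotone
coupling (with probability `label_correlation` a consecutive label pair
shares one uniform draw — this preserves both marginals exactly while
inducing co-occurrence), and planted informative features whose occurrence
probability rises by `signal` when their assigned label is present, among
noise features at the same base rate. Defaults mimic the scale of a real
outpatient stomach-disease corpus (436 records, 323 features, 49 labels,
mean cardinality 2, base rate 0.1, signal 0.6, Zipf exponent 1.2);
unit tests shrink everything.

What the generator does **not** emulate: real symptom vocabulary and its
semantics, co-occurring symptom clusters (features are conditionally
independent given labels), label hierarchies, and annotation noise. A
green test on synthetic data establishes algorithmic correctness and the
direction of effects (e.g. that selection helps when noise dominates), not
clinical performance. Two known interactions: the guarantee that every
record keeps at least one label redistributes a little probability mass
from empty draws, so pairwise independence at `label_correlation = 0` is
exact only in the limit where empty label draws are rare; and the
guarantee of at least one symptom per record adds single random features
to otherwise-empty rows.

`textualize()` injects synthetic spelling variants together with the
dictionary that undoes them, so the standardization stage can be tested by
round-trip: vectorizing the standardized variant corpus reproduces the
original matrices exactly.

## Cross-validated pipeline

`run_pipeline()` chains the stages with 5-fold cross-validation and
reports per-fold values plus across-fold mean and sample standard
deviation. Feature selection is refit inside each training fold — whether
the original protocol selected before or inside CV is unstated, and
per-fold refit is the leakage-free choice. Folds use iterative multi-label
stratification (rarest label first, each positive record to the fold with
the greatest remaining demand) so rare syndromes are spread across folds;
plain shuffling is available. `run_ablation()` runs the
selection-plus-cascade arm and the all-features cascade arm on identical
folds and seeds and emits the paired table.

## Limitations

* Forest training is single-threaded; corpora far beyond a few thousand
  records will be slow.
* The confidence formula of the measure-aware reuse mechanism is a proxy
  (see above), not a reproduction of the original's unpublished rule.
* Terms must arrive pre-tokenized; no Chinese NLP segmentation and no
  symptom-database lookups are performed.
* The published headline CV scores on the two real clinical corpora are
  not reproduced here: the corpora are not redistributable with the
  package, and the scores are protocol-underspecified. The package's
  correctness surface is its oracle-checked operations and
  direction-of-effect properties on synthetic data.
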