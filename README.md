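# syndforest

Multi-label syndrome differentiation for clinical symptom records: a
Pearson-similarity multi-label ReliefF feature filter feeding a deep
forest cascade, with the full set of multi-label evaluation measures, a
synthetic record generator with planted ground truth, and a
cross-validated end-to-end pipeline.

## The problem and who this is for

In traditional Chinese medicine, one clinical presentation usually maps to
*several* co-occurring syndromes, so computational syndrome
differentiation is multi-label classification on small, sparse,
high-dimensional corpora: a few hundred records, hundreds of symptom-term
features (mostly irrelevant to any given syndrome), and long-tailed label
frequencies. This package is for researchers modelling such data — or any
small-sample multi-label text-derived data with the same shape.

## The method

Records are cleaned (degenerate records dropped, identical presentations
merged into multi-label records), synonym-standardized, and vectorized to
`X` (n × f, binary or TF-IDF) and `Y` (n × m binary). Two components then
carry the modelling weight:

**Similarity-weighted multi-label ReliefF.** Every record is visited once
as a probe. Features are scored down by their similarity-weighted,
range-scaled differences to the probe's *hit* neighbors (same label set)
and up by the prior-weighted differences to each class's *miss* neighbors:

    W_p -= Σ_j sim(t, Hit_j) d(p, x_t, Hit_j) / (n Σ_j sim(t, Hit_j))
    W_p += Σ_{C∉LS_t} [P(C)/(1 − P(C_xt))] ·
           Σ_j sim(t, Miss_Cj) d(p, x_t, Miss_Cj) / (n Σ_j sim(t, Miss_Cj))

with `sim = 1/(1 − ρ)`, the reciprocal Pearson distance (clamped near
ρ = 1). The top-weighted features go forward.

**Multi-label deep forest cascade.** Each layer pairs a
predictive-clustering forest with a per-label-Gini forest; their
out-of-fold score vectors (n × 2m) are concatenated to the input of the
next layer. A measure-aware reuse rule keeps the previous layer's
representation for low-confidence records, and layer growth exits once
the tracked measure (average precision by default) has not improved for
three consecutive layers. Scores above 0.5 become label decisions; an
all-zero row gets its top-scoring label.

Evaluation covers hamming loss, one-error, coverage (1/(nm)
normalization, as this method family prints it), ranking loss, average
precision, macro-AUC, and the five set measures mlACC/mlPRE/mlREC/mlF1/ACC
— every one verified against brute-force enumeration oracles in the test
suite. See the methods vignette (`vignettes/syndrome-differentiation.Rmd`)
for the modelling decisions and their rationale.

## Worked example

```r
library(syndforest)
options(syndforest.verbose = FALSE)

# synthetic corpus: 200 records, 5 syndromes, 8 informative among 80
# features, long-tailed labels with pairwise co-occurrence
syn <- synth_generate(synth_config(n = 200, f_informative = 8, f_noise = 72,
                                   m = 5, labels_per_record = 1.8, tail = 1,
                                   seed = 42))

fw <- ml_relieff(syn$features, syn$labels, k = 10)
print(fw, n = 5)
#> <feature_weights> 80 features; top 5:
#> sym0002 sym0008 sym0007 sym0003 sym0004
#> 0.74849 0.73575 0.70224 0.68088 0.54689

sel <- select_features(fw, 20)
sum(syn$features$feature_names[sel] %in% syn$truth)
#> [1] 8        # all 8 planted informative features recovered

fold <- make_folds(syn$labels, k = 5, seed = 7)
tr <- fold != 1; te <- fold == 1
model <- cascade_fit(syn$features$X[tr, sel], syn$labels$Y[tr, ],
                     cascade_config(n_trees = 20, n_folds = 3, seed = 7))
model
#> <cascade_forest> 4 layers grown, depth 1 selected by average_precision
#>   (history: 0.8796, 0.8695, 0.8656, 0.8777)

pred <- predict(model, syn$features$X[te, sel])
evaluate_all(syn$labels$Y[te, ], pred$labels, pred$scores)
#>              measure value direction
#> 1       hamming_loss 0.176     lower
#> 2          one_error 0.143     lower
#> 3           coverage 0.238     lower
#> 4       ranking_loss 0.109     lower
#> 5  average_precision 0.879    higher
#> 6          macro_auc 0.806    higher
#> 7              mlACC 0.651    higher
#> 8              mlPRE 0.833    higher
#> 9              mlREC 0.706    higher
#> 10              mlF1 0.765    higher
#> 11               ACC 0.405    higher
```

Reading the output: the filter ranks the planted informative features at
the top (weights ≈ 0.5–0.75 against near-zero noise weights); the cascade
grew four layers and kept depth 1, where out-of-fold average precision
peaked at 0.88; on the held-out fold the model ranks a true syndrome first
for 86% of records (one-error 0.143) and reproduces the exact label set
for 40% (ACC 0.405) — exact-match is the strictest of the eleven measures.

For file-based corpora, `run_pipeline()` / `run_ablation()` handle the
whole chain with 5-fold CV (feature selection refit inside each training
fold) and write per-fold and mean ± sd metric tables, the feature-weight
report, and the per-label AUC table. A thin CLI wraps the same calls:

```sh
Rscript inst/cli/syndforest.R run --records records.tsv --seed 1 --out out/
Rscript inst/cli/syndforest.R ablate --records records.tsv --out out/
```

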