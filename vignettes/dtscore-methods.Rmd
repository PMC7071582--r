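---
title: "Methods: druggability scoring by positive-unlabeled random-forest bagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: druggability scoring by positive-unlabeled random-forest bagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`dtscore` treats drug-target prioritization as a positive-unlabeled (PU)
classification problem. The only trusted labels are the *positives* —
proteins with at least one approved drug for the indication of interest.
Everything outside the approved-target set is *unlabeled*: it contains
future targets as well as genuinely undruggable proteins. Two assumptions
drive the design:

1. proteins similar (in feature space) to approved targets are more likely
   to be viable targets; and
2. a uniformly sampled subset of the unlabeled pool is, on average, a
   usable stand-in for a negative class, because true-but-unknown targets
   are rare in the pool.

Under assumption 2, training one classifier against one pseudo-negative
sample is noisy; bagging over many samples (`n_models`, default 10,000)
averages that noise away. Each replicate trains a balanced random forest
(positives vs an equally sized pseudo-negative sample drawn without
replacement) and predicts every protein; the final score is the mean
predicted probability, and feature importance is the mean decrease in Gini
averaged the same way. The averaged score is interpretable as similarity to
the approved-target class, not as a calibrated probability of approval.

Validation uses a *clinical holdout*: proteins targeted only by
clinical-trial drugs of the matching indication and by no approved drug.
These were never seen in training, and under assumption 1 they should score
high; the ROC/AUC of holdout-vs-pool quantifies that.

## Feature construction

* **Annotation features** are taken as input (sequence-derived predictors
  are upstream of this package). Categorical columns are one-hot encoded —
  the encoding is our choice; any full-rank encoding is equivalent for
  tree learners up to split granularity.
* **Tissue-specificity entropy.** For expression profile `e_ig` over `N`
  tissues with total `S_g`, `E(g) = −(1/S_g) Σ_i e_ig log2(e_ig/S_g)`,
  in bits: 0 for a single-tissue gene, `log2(N)` for a uniform one. We set
  `0·log2(0) = 0` (the standard continuity convention) and return a missing
  value when `S_g = 0`; per-gene entropies are averaged over the expression
  sources in which the gene is non-missing. Sources are *not* forced onto a
  common tissue set: entropy is a per-source summary on its own tissue
  panel and the average is a compromise between panels, so `N` (and hence
  the upper bound) may differ between sources.
* **Network centralities.** The scored interaction table is deduplicated
  (unordered pairs, max score kept), the top `edge_fraction` (default 0.1)
  of edges by score is retained — ties with the cutoff score are all kept,
  so the result is independent of input order — and the remaining graph is
  treated as simple, undirected and unweighted: the score is a confidence,
  not a distance, so it is used only for thresholding. Five features are
  computed: degree; unnormalized betweenness (normalization is immaterial
  because all features are min–max scaled later); classical closeness per
  connected component, `(n_comp−1)/Σ d`, with isolated nodes at 0 (the
  harmonic variant was rejected to stay with the classical definition);
  PageRank at the conventional damping 0.85; and eigenvector centrality of
  the largest component scaled to maximum 1 with 0 elsewhere (the
  eigenvector is only defined up to components; the largest-component
  convention is ours).
* **Ontology rank scores.** Per category, every gene set is tested for
  over-representation of the positive *training* set (one-sided Fisher
  exact test, i.e. the hypergeometric upper tail) against the background of
  all proteins in the feature matrix. Overlapping sets are ranked 1..k by
  ascending p-value (ties broken lexicographically by set id, for
  determinism); zero-overlap sets all receive the category's maximum rank
  (its total set count). A protein is scored by the mean of its three best
  ranks, padded with the maximum rank when it belongs to fewer than three
  sets. The "mean of top 3" aggregation and the three categories entering
  as three separate columns are documented choices where several readings
  were defensible. Because ranks are computed from training positives only,
  the clinical holdout never leaks into the features. Rank scores are
  bounded by the category size, so they are min–max scaled but not
  log-transformed.

After assembly (outer join on protein id), missing numeric entries are
imputed with the column median computed over proteins *outside* the
positive set, so imputation cannot import positive-class statistics into
the background. Columns flagged heavy-tailed — by default the unbounded
centralities degree, betweenness and PageRank — are transformed with
`log(1+x)` rather than `log(x)` so exactly-zero centralities (isolated
proteins) stay representable; the log base is irrelevant after scaling.
Min–max scaling maps constant columns to zero (the defining formula divides
by zero there, and a constant column carries no information either way) and
drops all-missing columns with a warning.

## Target sets

The catalog is partitioned as: positives = targets with an approved drug
matching the indication filter; clinical holdout = targets with a matching
clinical-trial drug and *no* approved drug of any indication; negative pool
= universe minus all approved-drug targets (any indication) minus the
holdout. Excluding approved targets of *other* indications from the pool
keeps known-druggable proteins out of the pseudo-negative samples while
also keeping them out of the positive class. Targets whose drugs were all
withdrawn remain in the pool. Indication matching is a case-insensitive
regular expression: the manual curation behind real catalogs cannot be
reproduced programmatically, so the filter is configuration.

## The random-forest learner

No random-forest implementation is available in this package's dependency
environment, so `src/rf.cpp` provides a compact one: CART trees grown to
purity (nodesize 1), Gini splitting over `mtry` uniformly sampled candidate
features per node, bootstrap bagging, out-of-bag (OOB) error, and
mean-decrease-Gini importance accumulated as the impurity reduction of each
split, divided by the number of trees. Probabilities are averaged leaf
frequencies. The learner uses its own xorshift64* RNG seeded by splitmix64,
so forests are bit-reproducible across platforms and independent of R's
RNG state. Split ties are resolved by the first candidate found at the
sampled feature order with a 1e-12 dominance margin; thresholds are
midpoints between adjacent distinct values. Single trees with bootstrap
disabled and `mtry = p` are deterministic CART fits, which the test suite
compares against an exhaustive split-enumeration oracle.

`mtry` defaults to `floor(sqrt(p))`. An optional OOB-driven search
(`tune_mtry`) walks candidates up and down by a multiplicative
`step_factor`, accepting a move only when the relative OOB improvement is
at least `improve` (default 0.01). A step factor must exceed 1 to generate
new candidates; published descriptions of this procedure sometimes quote a
step of 0.01, which is inconsistent with the multiplicative semantics, so
the default here is 1.5 and the parameter is exposed in configuration.

## Determinism

Replicate `m` of a run with master seed `s` uses the derived seed
`derive_seed(s, m)` (Lehmer-style mixing modulo 2^31−1) for both its
pseudo-negative sample and its forest. Results are therefore independent of
execution order and worker count; the ensemble averages per-replicate
results in index order, and two identical runs produce byte-identical score
files. All scenario generation runs under a locally scoped R RNG seeded
from the scenario config.

## The synthetic world

`generate_scenario()` emits all five inputs with controllable ground truth:

* informative continuous features are mean-shifted by `effect_size` on the
  standardized scale (so the knob reads as Cohen's d), for positives *and*
  clinical-holdout proteins — the clinical set resembling the approved set
  is precisely the premise that makes holdout AUC a recovery metric;
* one categorical feature's level frequencies are tilted by
  `exp(effect_size · (−1, 0, 1))`, emulating enrichment of classes such as
  enzymes or membrane proteins among targets;
* the interaction network grows by preferential attachment in which a
  positive/clinical protein's attachment weight is multiplied by
  `1 + network_hub_bias`; edge scores are uniform, so the top-10% filter is
  exercised but keeps a representative subgraph;
* half of each ontology category's sets are "cancer-like": positives and
  clinical proteins join them with membership probability multiplied by
  `ontology_enrichment`;
* tissue-specific genes have one dominant tissue; positives/clinical are
  tissue-specific with probability multiplied by `tissue_specificity_bias`.
  This knob is not part of the minimal effect-size triple but must exist so
  the null scenario ("all effects off") can switch the bias off; the
  default is 3, a level at which target entropy distributions are visibly
  left-shifted without being disjoint from the background;
* two expression sources share the specificity assignment but have
  independent noise, and two background genes are silent in one source to
  exercise the missing-entropy path; a sprinkling of reciprocal duplicate
  edges exercises pair deduplication.

Defaults (500 proteins, 30 positives, 20 clinical, 5 informative of 30
features, effect size 1.0, hub bias 2.0, enrichment 5.0, seed 1) define the
standard recovery scenario; `null_scenario_config()` zeroes every effect.

What the generator does **not** emulate: correlated annotation features,
degree-dependent edge confidence, overlapping/hierarchical ontology sets
(no DAG structure), batch structure between expression sources, or any
sequence-level realism. A green recovery test therefore establishes that
the pipeline can find planted multivariate signal of realistic magnitude at
desk scale — not that it reproduces results on real proteome-scale
databases, which are deliberately outside this package's surface.

## A known artifact of PU averaging at desk scale

The score of a protein that served as a training pseudo-negative in some
replicates still includes those replicates' predictions (the averaging-all-
models convention). Training-set predictions of a purity-grown forest sit
near the training label, so each such replicate contributes a value near 0
for that protein. At production scale this is negligible (a pool of ~18,600
with 102 sampled per replicate touches each protein in ~0.5% of
replicates), but in the default synthetic world each pool protein is a
training negative in 30/445 ≈ 6.7% of replicates. Under the null scenario
this depresses pool scores relative to the never-trained clinical holdout
and inflates the "null AUC" above 0.5 by several hundredths — the
null-recovery band [0.4, 0.6] is checked at the package's default seed, and
at unlucky seeds the inflation alone can cross 0.6. The same mechanism
makes training positives' reported scores resubstitution scores, which is
intentional and matches how such scores are reported in practice.

## Numerical and degenerate-input conventions

* Entropy: `0·log2(0) = 0`; `S_g = 0` gives NA; values are clamped to
  `[0, log2(N)]` against floating-point fuzz.
* Fisher p-values come from `stats::phyper` upper tails; no multiple-testing
  correction is applied because only the rank order of sets is used.
* PageRank uses igraph's exact (algebraic) solver; the reported vector sums
  to 1 over graph nodes, and proteins absent from the filtered graph get 0
  in all five centrality columns.
* ROC/AUC uses the Mann–Whitney rank formulation with ties counted 1/2;
  the curve is a threshold sweep with one point per distinct score.
* Wilcoxon rank-sum is used for continuous features, chi-squared without
  continuity correction for categorical indicators; constant features are
  skipped with a warning.
* LOOCV classifies held-out examples at threshold 0.5, natural for balanced
  training sets; holdout evaluation uses the entire negative pool rather
  than a sample, trading a small optimism in pool contamination for
  determinism.
* Spearman's rho is the correlation for comparing score vectors (bounded,
  skewed scales make rank correlation the robust choice).

## Limitations

The method is indirect: it scores similarity to known targets and knows
nothing of binding pockets or structures. Scores are not calibrated
probabilities. Feature importances are Gini-based and inherit its bias
toward features with many distinct values; they are averaged over
replicates but not corrected for correlated feature blocks (centralities,
ontology categories), so importance mass can spread within a block. The
ontology scoring rewards membership in sets enriched for *current* targets,
which imports historical bias of the training catalog into the score.
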