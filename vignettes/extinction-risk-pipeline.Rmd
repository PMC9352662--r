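---
title: "Predicting extinction-risk probabilities for Data Deficient species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting extinction-risk probabilities for Data Deficient species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The IUCN Red List assigns most assessed species a risk category, but a
substantial minority are Data Deficient (DD): there is not enough
information to place them anywhere between Least Concern and Critically
Endangered. DD species are routinely dropped from conservation analyses,
which biases Red-List-derived indices wherever DD species are not missing
at random. `perisk` implements, at desk scale, a pipeline that learns the
relationship between spatially summarized stressors and the binary
threatened / not-threatened reclassification of data-sufficient (DS)
species, and transfers it to DD species as a probability of being
threatened by extinction (the *PE score*).

Because the real inputs (IUCN range maps, GBIF/OBIS occurrences, hundreds
of global stressor layers) are large external resources, the package pairs
the pipeline with a *synthetic world generator* whose threat-generating
process is known exactly. Every stage of the pipeline can therefore be
validated against ground truth, something impossible with the real data.

## The synthetic world

`generate_world()` draws, under a single seed that fans out into per-stage
substreams:

* **Grid.** The global half-degree grid (720 x 360 cells), row-major from
  the north-west corner, half-open cells in both axes. All rasters,
  rasterized ranges, occurrence binning and aggregation maps share this one
  `grid_spec()`.
* **Stressor layers.** `n_causal = 3` spatially autocorrelated fields
  (white noise smoothed with a Gaussian kernel, sd 3 cells truncated at
  3 sd, periodic boundaries, re-standardized), `n_noise = 20` white-noise
  fields, and `n_count = 2` sparse Poisson count layers standing in for
  point infrastructure such as dams and power plants. Autocorrelation in
  the causal layers is what makes zonal summaries over a species range
  informative; the lag-1 neighbour correlation (`moran_lag1()`) is > 0.3
  for smoothed layers and approximately 0 for noise layers.
* **Species.** 2000 species with axis-aligned elliptical ranges whose
  areas are log-uniform between 2 and 2000 cells, random aspect ratios,
  centers within +/-65 degrees latitude (avoiding polar distortion of the
  lon/lat ellipse approximation; longitude wrap-around is not modelled).
  A nested taxonomy (2 kingdoms / 4 phyla / 8 classes / 40 families) is
  drawn with uneven family sizes; domains (terrestrial / freshwater /
  marine) are random with P(marine) = 0.3.
* **Ground truth.** Each species' causal features are the *means of the
  three causal layers over its range cells*, z-scored across species. The
  true threat probability is `plogis(-1 + 1.5 z1 - 1.0 z2 + 1.0 z3)` and
  the true status is a Bernoulli draw. Threatened species get a category
  uniformly from VU/EN/CR, others from LC/NT — the pipeline only consumes
  the binary reclassification, so finer category structure would be
  untestable decoration.
* **Label erosion.** 20% of species are relabelled DD (about the share of
  DD species among those with range maps in the real spatial data), with
  sampling weights `exp(-z(log range cells))` so that DD species are
  biased toward small ranges, as described for the real Red List; the bias
  strength is a modelling knob, not an empirical value. 1% become EX/EW
  and 5% are flagged as outdated assessments, so the exclusion filters
  have something to act on. True status and probability are retained for
  validation.
* **Occurrences.** Negative-binomial point counts (mu 25, size 1, plus an
  8% structural-zero share) placed uniformly inside random range cells,
  years 2010-2020. Species without occurrences exercise the
  missing-then-imputed path that affects about 5% of values in the real
  feature table.
* **Countries.** A seeded rectangular partition of the grid (24 x 12
  blocks) stands in for country borders; `n_native_countries` counts the
  blocks a range touches.

What the generator does *not* emulate: real biogeography (land/sea masks,
coastlines), correlated stressor bundles, phylogenetic signal in threat
status beyond what the causal layers induce, spatially clustered sampling
effort, or the tail of very large (>2000-cell) ranges. Passing tests on
this world therefore show that the pipeline recovers a known signal of the
assumed form through the whole chain — not that the real-world accuracy of
any particular published model is reproduced.

## Feature extraction

* **Range rasterization.** A cell belongs to a range iff its rectangle
  intersects a native + extant polygon with positive area. The
  "any-intersection" rule (not center-in) keeps small-range species on the
  map; a centroid fallback guarantees a non-empty cell set. Seasonal
  polygons are unioned before extraction — the union is the conservative
  exposure envelope when the combination rule is not otherwise specified.
  For convex polygons a row-band scan is used (clip the polygon to each
  latitude band; every cell whose open x-interval overlaps the band
  slice's x-extent intersects it with positive area); non-convex input
  falls back to per-cell clipping. Both paths are tested against each
  other and against an independent geometry engine.
* **Zonal statistics.** Min / max / mean / median of each non-count layer
  over the range cells and, separately, over the occurrence cells; sums of
  count-like layers over the range; counts of occurrence points and
  occurrence cells; range extent both as a cell count and as geodesic
  (WGS84 ellipsoid) km^2, since the natural unit of "range extent" is
  ambiguous. Zonal summaries over an all-missing cell set are missing, and
  occurrence-derived columns of species without occurrences are missing —
  never zero, which would fabricate signal.
* **Imputation.** Missing numeric entries are replaced by uniform draws
  from the *training-observed* values of their column (`make_imputer()` /
  `apply_imputer()`), the classical random-value scheme. The imputer is
  fitted on training rows only and applied unchanged to test and DD rows,
  so no test-set statistics leak into training.

## Partitioning

Categories reclassify as VU/EN/CR = threatened; LC, LR/LC, LR/CD, NT =
not threatened; DD held out; EX/EW excluded. Outdated assessments are
removed unless a taxonomic class would drop below five records, in which
case outdated records are re-added in lexicographic id order up to five —
the order is a tie-break the rule itself leaves open.

The 75/25 split stratifies on the cross of family and the marine flag
(the strictest reading of "within both taxonomic families and
environmental domains"; crossing degrades gracefully because singleton
cells go to train). Within each (family, marine, label) cell a seeded
shuffle precedes allocation; cell quotas use largest-remainder rounding
with ties broken by stratum id, so the global train fraction hits 75% up
to a single species. Oversampling of the minority class (duplication with
replacement until balance) happens *only* inside CV training folds and in
the final refit — never in validation folds or the test set.

## Feature selection

A one-shot shadow-feature filter: each of 50 runs duplicates every
feature, permutes the copies, fits a seeded random forest (64 trees,
out-of-bag permutation importance) on originals + shadows, and scores a
hit for every feature whose importance strictly beats the best shadow.
Hits are tested two-sided against Binomial(50, 1/2) at alpha = 0.01:
significantly above 25 confirms, significantly below rejects, the rest
stay tentative and are dropped. Design choices worth stating:

* One-shot rather than the iterative-elimination variant: it matches the
  "relevant at the 99% confidence level after 50 runs" framing and is far
  easier to test.
* Out-of-bag *permutation* importance rather than impurity importance,
  which is biased toward high-cardinality features and would distort the
  shadow comparison.
* Categorical predictors enter as one-hot blocks; a block is confirmed if
  any member is, and confirmed blocks travel whole into the model.
* Columns are internally sorted to a canonical order and shadow
  permutations are seeded per column name, making decisions invariant to
  the order of feature columns.
* 64 trees per run is a desk-scale setting; the signal criterion is a
  rank comparison against the best of ~200 shadows, which stabilizes at
  moderate ensemble sizes, and decisions aggregate over 50 runs.

## The stacked super-learner

Four base learners (an L1-regularized logistic GLM via `glmnet`, a random
forest and an extremely randomized forest via `ranger`, gradient boosted
trees via `xgboost`) are fitted with stratified 10-fold CV; the held-out
fold scores populate the out-of-fold matrix. The meta-learner is a
logistic regression on that matrix with coefficients constrained
non-negative and an L1 penalty chosen by internal CV under the 1-SE rule
(`cv.glmnet(lower.limits = 0)`), so irrelevant base learners get exact
zeros and the ensemble stays sparse. Base models are then refit on the
full (oversampled) training set for prediction; the out-of-fold matrix is
used only to fit the meta-learner — the standard super-learner protocol.
The fixed four-learner roster replaces an AutoML search over hundreds of
candidates: same learner families, deterministic, desk-scale; deep neural
networks are omitted.

The binarization threshold maximizes F1 on the out-of-fold super-learner
scores (smallest optimum under ties). A threshold is needed to emit binary
labels at all, and max-F1 reproduces the asymmetric precision/NPV pattern
that a default 0.5 cut would not; it is exposed as a knob.

Two data partitions are trained: (1) all species together; (2) separate
marine and non-marine models (selection re-run per model; subsets under 50
training rows are skipped). The partition with the highest unweighted mean
AUC of cross-validated scores across taxonomic classes with at least five
labelled members wins; ties go to partition 1, and with no eligible class
the pooled AUC decides. Both partitions' predictions are emitted so the
choice stays inspectable.

## Evaluation

Confusion-matrix metrics are the elementary ratios (accuracy,
specificity, sensitivity, false positive rate, NPV, PPV) plus balanced
accuracy as the mean of specificity and sensitivity. Zero-denominator
metrics are reported as undefined (`NA`), never coerced to 0; display
rounding is half-up to 2 decimals. AUC uses the Mann-Whitney rank
formulation (ties count one half), AUC_PR is step-wise average precision
(no linear interpolation between PR points — it is exactly computable and
matches the convention of the usual toolkits), and the Gini coefficient
is `2 AUC - 1`. Permutation importance is the mean AUC loss on the test
set over 50 seeded permutations per feature, baseline computed once.
Validation on "re-assessed" species reveals the true labels of a held-out
10% of the DD species — the synthetic analogue of DD species receiving a
category in a later Red List version — and refuses any overlap with the
training ids.

## Aggregation

Presence is range-cell membership under the same rasterization rule used
for features. Per cell, the package reports the fraction of DD species
present that are predicted threatened (masked, not zero, where no DD
species occur) and the percent change in mean PE score when DD species
are pooled with DS species, `100 (mean_all - mean_ds) / mean_ds`, masked
where no DS species occur. DS species contribute their *model-predicted*
PE score rather than a 0/1 from their category: it keeps both populations
on the same scale and the alternative is a switchable choice
(`percent_change_map()` takes whatever DS scores you hand it). Masking is
encoded as raster nodata in the `.asc` outputs.

## Orchestration and reproducibility

`run_stage()` / `run_pipeline()` chain simulate → extract → split →
select → train → evaluate → aggregate in a run directory; each stage
writes a JSON manifest with the seed, a config hash, and md5 sums of its
inputs and outputs, and a missing upstream artifact raises an error
naming the stage to run. A run is a pure function of (config, seed): all
stochastic steps (layer noise, geometry, label draws, splits, folds,
oversampling, imputation, forests, boosting, permutations) derive their
seeds from the single config seed via labelled substreams
(`stage_seed()`), and reruns are hash-identical. Rasters are written as
ESRI ASCII grids — a plain-text raster format any GIS reads — ranges as
GeoJSON, tables as CSV.

## Problem sizes used by the tests

The test-suite worlds are the package's own choice of problem size: the
full default world (2000 species, 0.5-degree grid) is used for the
ten-replicate pipeline validation and a timed end-to-end run, while
module-level properties run on coarser global grids (2-15 degrees) and
smaller species counts where the property being checked does not depend
on scale. Multi-replicate checks scale down what can be scaled without
touching the stated study conditions: permutation importance uses 5
repetitions per feature in the replicate loop (50 in the default
pipeline), and sign-recovery uses 600-species worlds on a 2-degree grid
over 20 seeds. Where a checked quantity fluctuates from seed to seed
(test AUC), the tests assert it on the mean across the ten replicate
worlds.

## Known limitations

* Ranges are convex ellipses in lon/lat space; no wrap-around at the
  antimeridian and no polar ranges. The rasterizer itself accepts any
  simple polygon (with the exhaustive path), but the generator never
  produces concave or wrapped ranges.
* The Bayes ceiling of the default world is finite (the causal means over
  heterogeneous range sizes are leptokurtic, so the realized class
  separation sits below the iid-normal ideal); test AUCs around 0.80-0.87
  are the expected range, not a shortfall of the learners.
* The marine/non-marine contrast in the default world is label-neutral
  (same generating process), so partition 2 normally loses to partition 1
  — the partition-selection machinery is exercised by a dedicated
  opposite-effects scenario in the tests.
* Count-like layers are independent sparse Poisson fields, not clustered
  infrastructure.
* The meta-learner's 1-SE lambda can shrink the stack to a single base
  learner on easy worlds; that is intended sparsity, not failure.
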