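---
title: "Methods: ensemble suitability modelling and multi-species risk surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble suitability modelling and multi-species risk surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmrisk)
```

## The problem

Snakebite envenoming — like many zoonotic and vector-borne hazards — is
spatially structured: people are at risk where their settlements overlap the
suitable habitat of one or more dangerous species.  `sdmrisk` implements the
standard presence-only workflow for that question: screen environmental
predictors for collinearity, model per-species habitat suitability with an
ensemble of presence/background learners, evaluate each model on held-out
records, combine the per-species ensembles multiplicatively into a joint
risk surface, classify it, and count settlements per risk class.

Real analyses of this kind rest on external rasters (bioclim layers, NDVI,
human footprint, SRTM-derived terrain roughness) and on occurrence and
village gazetteers that are rarely redistributable.  The package therefore
treats a *virtual-species simulator* as a first-class module: it generates
landscapes with the same statistical structure (spatial autocorrelation,
moderate inter-layer correlation, low collinearity) and species whose true
suitability is known, so the whole pipeline is validated by recovery of a
known truth rather than by eyeballing maps.

## The synthetic landscape

`generate_landscape()` builds each layer as a linear mix of one shared and
one layer-specific Gaussian white-noise field, smoothed with a separable
Gaussian kernel and standardized to mean 0, sd 1:

* **Spatial autocorrelation** comes from the kernel; its standard deviation
  (in cells) is the layer's `autocorrelation_length`.  This is the simplest
  reproducible stand-in for a geostatistical random field; it reproduces
  smoothness, not any particular covariance family.
* **Inter-layer correlation** comes from the mixing weight: a layer with
  target correlation $r$ weights the shared field by
  $\mathrm{sign}(r)\sqrt{|r|}$, so two layers with common target $r \ge 0$
  correlate pairwise at $r$ (exactly in expectation when autocorrelation
  lengths are shared; approximately otherwise, and the package's tests
  verify realized correlations within ±0.15 of target on grids of
  100×100 and larger).
* The default stack has seven layers named for the predictor families of a
  typical venomous-snake analysis (bio4, bio12, bio15, bio17, NDVI, human
  footprint, SD of elevation), autocorrelation length 8 cells, and common
  target correlation 0.3.  For seven equicorrelated variables at $r = 0.3$
  every VIF is about 1.3 — comfortably "low collinearity", matching the
  1.3–3.3 range typical of screened real stacks.

The synthetic grid is projected equal-area with cell sizes in km, so cell
area is a constant and none of the tests need latitude weighting; the
`suitable_area()` helper still accepts per-row cos-latitude areas for
geographic grids.

**Virtual truth is logistic-linear**: suitability =
$\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j)$.  This deliberately
matches the GLM learner's family, so surface recovery is a meaningful test
with a well-defined optimum: a correctly working pipeline *must* recover it.

**Presence sampling** draws cells with probability proportional to true
suitability (records at cell centres, duplicates allowed; optional one-per-
cell thinning is off by default because the field practice it would emulate
is unknown).  Proportional sampling is a *weak* selection signal: even the
true model's AUC against uniform background is well below 1.  Passing tests
on these data therefore demonstrate rank recovery of the suitability field,
not the high AUCs one sees when presences are thresholded on suitability —
and by the same token they say nothing about sampling bias, spatial
clustering of records, or detection error in real data.

**Villages** are scattered uniformly over the valid extent (uniform cell,
then uniform position within the cell — exactly uniform on an equal-area
grid).  The default run uses 1,850 villages, a 1:100 scale-down of a
national gazetteer of 185,000, keeping the default problem desk-scale.

## Predictor screening

`compute_vif()` is the textbook $1/(1-R^2)$ with $R^2$ from an explicit OLS
regression of each column on the others; exactly collinear columns are
reported as `Inf` rather than raising an error, and `vif_screen()` drops
the worst variable and recomputes until all VIFs fall below the threshold.
The default threshold of 5 is deliberately permissive: published screens of
bioclim/NDVI/footprint stacks retain sets with VIFs up to about 3.3, and 5
retains any such set while still catching genuine redundancy.
`topographic_heterogeneity()` uses the sample (n−1) standard deviation in a
truncated window at edges, so the output extent equals the input extent;
nodata cells are excluded from neighbours' windows.  In the pipeline the
VIF screen runs on a random sample of 10,000 cells rather than all cells —
at the default grid this is most of the landscape, and on larger grids the
sampling error of a VIF at n = 10,000 is negligible.

## The five learners

All five methods sit behind one contract (`fit_sdm()` / `predict()`):
finite predictions in $[0, 1]$ for any finite input, fully determined by
(method, data, hyperparameters, seed).  Hyperparameters follow common
defaults and are all overridable: GBM 2,000 trees at learning rate 0.01 and
depth 3; RF 500 trees; GAM 4-df splines per term; GLM linear + quadratic
terms; the MaxEnt-style model uses linear, quadratic and 5-knot hinge
features with a lasso penalty chosen by internal 5-fold cross-validation.
The MaxEnt realization as a penalized logistic regression on
presence/background data is the established statistical equivalence, not a
reimplementation of the original software, and is not expected to be
bit-compatible with it.

For GLM, GAM and the MaxEnt-style model, background rows are down-weighted
so total background weight equals total presence weight; without this the
intercept is dominated by the 100:10,000 prevalence and the fitted surface
saturates near 0.  Tree ensembles are left unweighted — their predicted
probabilities are prevalence-scaled, which is harmless because every
downstream use (AUC, TSS, Boyce, ensemble ranking) is rank-based or
threshold-optimized.  One background sample is shared by all five methods
per species; the number of pseudo-absence replicates is configurable in
principle but a single replicate is the default and the only tested path.

## Evaluation

* **AUC** is computed in Mann–Whitney rank form (ties ½).
* **TSS** uses the closed rule on the presence side (presence counts as
  predicted-present when score ≥ threshold), consistently in
  `tss_at_threshold()`, `max_sss_threshold()`, `binarize()` and
  `classify_risk()`.  `max_sss_threshold()` scans midpoints between
  consecutive distinct observed scores — every achievable confusion matrix
  with both classes non-empty corresponds to one midpoint — and breaks ties
  toward the lowest threshold (the more sensitive map).
* **Continuous Boyce index** defaults to 101 windows of width 10% of the
  landscape-score range, the established convention.  Windows with zero
  landscape mass are dropped; fewer than three usable windows is an error;
  a constant prediction vector returns `NA` with a warning (the index is
  undefined), and a constant P/E profile returns 0.  Because
  `evaluate_model()`'s inputs are point matrices, its Boyce reference
  defaults to predictions on the full background matrix — background is a
  uniform sample of the extent, so this *is* the landscape reference
  distribution; a caller with the full cell matrix can pass
  `landscape_scores` explicitly (the pipeline does, for ensembles).
* **Permutation importance** is $1 - |\mathrm{Pearson}\ r|$ between
  predictions on the original matrix and on a single-column-permuted copy,
  averaged over permutations (default 10) — Pearson, not Spearman,
  following the convention of the ensemble-modelling platforms this
  workflow mirrors.  The pipeline evaluates importance on the presences
  plus a 1,000-row background subsample; with ≥ 1,100 rows the correlation
  estimate is stable and the cost of 5 methods × 7 variables × 10
  permutations stays in seconds.

Evaluation in the pipeline is reported both per method and for the
ensemble; which level a given published figure refers to is often
ambiguous, so both are emitted.

## Ensemble, risk surface, classification

The per-species ensemble is the unweighted mean of the five surfaces by
default; a TSS-weighted mean is available (`ensemble_weighting = "tss"`)
since committee averaging by skill is the other common convention.  The
joint risk surface is the raw cellwise product of the per-species
ensembles, kept unnormalized in $[0, 1]$; a min–max rescaled copy is
written for display only, because the product of four suitabilities is
numerically small (order $10^{-2}$ even where all four are high) and a
fixed colour scale would hide its structure.

The three-class risk map uses `t_suitable` = the species' maxSSS threshold
(computed from the ensemble's held-out scores) and `t_high` = the midpoint
between `t_suitable` and the observed surface maximum.  The high/moderate
split has no canonical definition in the literature this workflow comes
from; the midpoint rule is monotone, scale-free and explicit in every run
manifest, and both thresholds are plain config keys.  Suitable area is
taken from the binary (maxSSS) map, i.e. "suitable habitat area" rather
than "any-risk area"; the class map is the configurable alternative.

## Pipeline determinism

Every stage seed is `stage_seed(master, stage, species)` — a small
polynomial hash below $2^{31}$ — so adding a species never perturbs another
species' draws, and a rerun with the same master seed reproduces every CSV,
JSON and ASCII-grid artifact byte for byte.  The run manifest records the
package version, master seed, full configuration and derived thresholds,
and suffices to re-run an identical analysis.

## Problem sizes

The package's own validation uses: 200×200 grids with 7 layers, 100
presences, 10,000 background points and an 80/20 split for surface-recovery
checks (10 seeds; the per-species ensemble must reach Spearman ρ ≥ 0.8
against truth, and permutation importance must rank the strongest true
coefficient first, in at least 9 of 10); and the default pipeline
configuration — 150×150 grid, four virtual species with occurrence counts
89, 68, 54 and 37, all five methods, 10,000 background points, 1,850
villages — for the end-to-end determinism check.  These sizes were chosen
as the smallest at which the spatial and statistical structure is
representative; all are plain config entries.

## Known limitations

* The simulator reproduces correlation and smoothness, not real climate
  physics; virtual truths are logistic-linear, so it cannot probe how the
  ensemble handles strong interactions or thresholds in the true response.
* No spatial cross-validation: the 80/20 split is random, and with
  autocorrelated landscapes that flatters all models equally; the recovery
  tests compare surfaces to truth and are immune, but the reported AUCs
  should be read accordingly.
* Presence records are simulated without sampling bias or detection error.
* One pseudo-absence replicate per species; no hyperparameter tuning
  studies; no population weighting of village exposure.
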