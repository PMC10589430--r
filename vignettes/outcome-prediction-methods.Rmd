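---
title: "Predicting post-stroke motor outcome in mice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting post-stroke motor outcome in mice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokepredict)
```

## The problem

After transient middle cerebral artery occlusion (MCAO) in mice, the
functional outcome — how well an animal uses its paretic forepaw weeks
after the stroke — varies widely even under standardized surgery.
`strokepredict` implements a pipeline that asks which measurements taken
early after stroke predict that outcome best, and which parts of the
lesion carry the predictive information. Three candidate predictors are
compared throughout:

* **lesion volume** — edema-corrected lesion volume measured within the
  atlas coordinates (mm³);
* **segmented MRI** — the vector of per-region lesion percentages across
  an anatomical atlas, i.e. the lesion's topography;
* **subacute deficit** — the degree of early motor impairment itself.

The behavioral readout is the staircase test of skilled reaching: the
percentage of presented food pellets an animal retrieves per paw per day.
Performance is normalized to each animal's own pre-stroke baseline (mean
over days −7..−1), and two post-stroke phases are summarized per animal:
the dynamic **subacute** phase (days 2–6) and the stable **residual**
phase (days 12–21), with a 5-day gap so the dynamic phase has ended.
Five mRS-like severity grades are assigned from the deficit.

## The prediction-error statistic

All predictors are evaluated with the same repeated-split scheme: the
cohort is partitioned `n_models` times (default 50) into two-thirds
training / one-third test; a bagged regression-tree ensemble is fitted on
the training animals only and the absolute test-set errors are collected.
Per model the *median* absolute error and its quartiles are computed; the
**prediction error (PE)** is the mean of the per-model medians, reported
in percentage points of baseline performance, with quartiles and IQR
averaged the same way. All predictor sets share the *identical* splits
(asserted through a split checksum), so comparisons are paired.

Forest hyperparameters follow the standard regression defaults — 500
trees, `ceiling(p/3)` candidate features per split, unlimited depth,
minimum node size 5 — and are configurable via `rf_control()`. The
ensemble backend is `ranger`, whose permutation importance is computed
per tree on its out-of-bag samples.

## Region selection

`oob_importance()` averages the out-of-bag permutation importance of
every atlas region over the repeated model fits (averaging over fits
reduces seed dependence); ties in the ranking break by ascending region
id. Regions with above-zero mean importance form the positive subset.
`incremental_inclusion()` then rebuilds the predictor from the top-`k`
regions for `k = 1..K` on the same splits and locates the first local
minimum of the PE curve.

Two local-minimum rules are provided. The strict rule
(`first_local_minimum(pe, tol = 0)`) takes the smallest interior `k` with
`PE(k) ≤ PE(k−1)` and `PE(k) < PE(k+1)`, resolving plateaus to their
smallest `k` and never accepting an endpoint. On repeated-split PE
curves, however, adjacent-`k` values jitter by a few tenths of a
percentage point, so the strict rule frequently fires on a shallow dip
while the curve is still clearly falling. `incremental_inclusion()`
therefore reports the first *relevant* local minimum by default
(`tol = 0.025`): a local minimum additionally has to lie within 2.5 % of
the best PE reached anywhere on the curve. The strict primitive remains
available and is the right tool for noiseless curves.

Severity-stratified PE (`stratified_pe()`) recomputes the per-model
medians within each residual severity grade. The pipeline report
stratifies the segmented-MRI residual model: imaging-based predictors
show the severity dependence of accuracy most cleanly, because the
early-behavior predictor partially tracks the same late measurement it is
asked to predict.

## The synthetic cohort generator

No animal data ship with the package. `simulate_cohort()` generates a
cohort with the statistical structure the analysis assumes, with known
ground truth, so every claim the test suite makes is a parameter-recovery
statement. What it emulates, and what it does not:

**Atlas.** `build_toy_atlas()` builds a mirror-symmetric ellipsoidal
brain (default 32³ voxels at 0.2 mm) partitioned into 60 regions: per
hemisphere 10 deep, striatum-like regions and 20 cortex-like shell
regions, parcellated by k-means on voxel coordinates. This stands in for
a full mouse brain atlas at desk scale; it reproduces the
subcortical-core / cortical-shell nesting of the MCAO territory, not
mouse neuroanatomy.

**Lesions.** `simulate_lesion()` grows a connected lesion from the
striatal core by stochastic voxel accretion. The cortical shell only
becomes reachable once the lesion exceeds 18 % of the hemisphere, so
every cortical lesion also carries striatal damage. Target size is the
`latent_severity` quantile of a lognormal whose mean fraction of the
hemisphere is 0.15 / 0.32 / 0.50 at 30 / 45 / 60 min occlusion with CV
0.75 / 0.50 / 0.30 — longer occlusions give larger, relatively more
homogeneous lesions, which is the direction seen in occlusion-time
comparisons. Each animal additionally draws a random preferred growth
direction (`anisotropy_kappa = 3.5`): lesions of equal volume then differ
in *which* regions they reach. This directional territory variability is
what makes topography informative beyond volume; with `anisotropy_kappa
= 0` and a closed shell gate the generator produces uniform subcortical
infarcts in which volume is a sufficient statistic.

**Deficit.** The acute deficit is a shifted–rescaled logistic in the
weighted damage over 14 informative regions (2 peripheral deep + 12
near-core shell regions by default; weights configurable), plus Gaussian
noise on the logit scale (`acute_noise_sd = 0.35`). Zero damage maps to
zero deficit, so an all-zero weight vector yields sham-like MCAO
trajectories. The residual deficit is a deterministic recovery curve of
the acute deficit, `d · (0.3 + 0.4 d)`, plus Gaussian noise whose SD
scales as `0.08 · (0.3 + 2.5 d²)`: mildly affected animals recover
almost completely and predictably, severely affected animals split into
recoverees and non-recoverees. This heteroscedastic recovery is the
generative encoding of two empirical observations — the early deficit is
the best predictor of the late one, and severe residual deficits are the
hardest to predict.

**Trajectories.** Daily paretic-paw retrieval probability is
`plateau × (1 − deficit(t))`, with the deficit relaxing exponentially
(`recovery_rate = 0.15`/day) from the acute to the residual level;
day-level counts are binomial with 20 pellets per side per day (the pellet
count is not reported for the original assay; it only sets measurement
granularity). The non-paretic paw gets a smaller, faster-resolving dip;
sham animals get noise-only trajectories; training (days −21..−1) ramps
exponentially to the plateau. Days 0–1 are absent (surgery and imaging).

**Covariates.** Genotype (15 labels) and surgeon (2) are assigned
uniformly; surgeons carry equally spaced additive volume offsets spanning
`surgeon_effect_mm3` and genotypes carry N(0, `genotype_effect_sd`)
offsets. Setting both to zero provably removes any covariate volume
signal.

**Determinism.** The cohort is a pure function of its configuration: the
master seed spawns one substream per animal (`derive_seed()`, a Lehmer-
style integer hash), so regenerating part of a cohort never perturbs the
rest, and two runs with the same configuration are bit-identical.

What the generator does *not* model: hemodynamics, T2w signal formation
or image registration (masks are generated directly in atlas space),
mortality and exclusion, edema (its masks are symmetric, so the
hemisphere-ratio correction is exercised as an identity plus dedicated
constructed-volume tests), and sickness behavior. Passing tests therefore
demonstrate that the pipeline recovers structure *of the kind the
generator encodes*; they cannot certify performance on real images with
registration error or rater variability.

## Numerical and design choices

* **Edema correction** uses the hemisphere-ratio strategy — in-atlas
  lesion volume scaled by contralateral/ipsilateral hemisphere foreground
  volume — exposed as a switch (`none | hemisphere_ratio`). The
  ipsilateral side is the lesion-majority hemisphere; an exact midline
  tie breaks to a configured side with a warning.
* **Percent scale.** Region involvement is stored on the 0–100 scale;
  every internal conversion divides by 100 explicitly. Counting uses
  exact integer voxel arithmetic before any division, and profiles
  conserve volume: `Σ pct_r/100 · vol_r` equals the in-atlas lesion
  volume to 1e-9 relative tolerance.
* **Severity thresholds** default to five equal 20-point bins on
  percent-of-baseline performance (≥80 → 0 … <20 → 4), half-open at the
  lower edge; they are configurable, strictly decreasing, and the grade
  is by construction monotone in the deficit.
* **Missing days** are averaged over, never imputed; an animal needs at
  least one valid day per phase and a positive baseline on both sides, or
  it is flagged and excluded (with its id reported).
* **Performance above baseline** is allowed (sham animals continue to
  improve with training); only the deficit is floored at zero.
* **Split sizes.** The test set is `round(n/3)` animals; with n = 215
  that is 72 test / 143 training animals per model.
* **Seed policy.** Split `i` uses `derive_seed(master, i)`; the tree seed
  of model `i` derives from that split seed; importance and permutation
  streams use further derived substreams. All seeds are recorded in the
  evaluation objects.

## Problem sizes used by the automated checks

The package defaults are 50 models × 500 trees. The test suite exercises
the same code paths at reduced, documented sizes so that the whole suite
runs comfortably on a single CPU: the Monte-Carlo acceptance sweep uses
20 master seeds × the full default cohort (n = 215) with 25 models × 150
trees and an inclusion curve up to K = 28; module-level Monte-Carlo
checks use cohorts of 48–120 animals with 4–10 models. The
`scripts/acceptance.R` entry point runs the full 50 × 500 defaults.

## Known limitations

* The toy atlas has 60 regions; the granularity of a real 700+-region
  ontology (and the corresponding 500+-region kept set) is not
  reconstructible at this scale, so region counts reported on synthetic
  cohorts are not comparable to atlas-scale studies.
* Lesion growth is a phenomenological accretion model; it reproduces
  incidence topology, volume distributions and direction variability,
  not perfusion physics.
* On small cohorts (n ≲ 100) the inclusion curve is noisy and the
  reported k\* can sit well below the number of truly informative
  regions; the region-selection claims in the test suite are made at the
  full cohort size.
* The replication-cohort workflow freezes the kept-region list and
  hyperparameters and refits per split by default; a transfer mode
  (train on the prediction cohort, test on the replication cohort) is
  also provided, since published descriptions of such validations are
  often ambiguous between the two.
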