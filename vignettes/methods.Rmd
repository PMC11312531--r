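---
title: "Methods: white-matter connectivity profiles of ventral temporal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: white-matter connectivity profiles of ventral temporal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`vtcwm` implements an end-to-end analysis of the white-matter connections of
functionally defined regions (fROIs) in human ventral temporal cortex (VTC):

1. **Sub-bundle extraction.** Streamlines from a whole-brain tractogram are
   assigned to an fROI by radial search: a streamline belongs to the fROI's
   sub-bundle iff either of its two *terminal* points lies within 3 mm
   (Euclidean, inclusive) of any fROI vertex on the gray/white interface.
   Interior points never count — the sub-bundle is the set of connections
   that *terminate* at the region.
2. **Connectivity profiles.** Both terminal points of every selected
   streamline are mapped to their nearest surface vertex (drop radius 3 mm;
   ties to the lowest index) and normalized to a density map summing to 1.
   Densities are aggregated over a 180-parcel-per-hemisphere cortical
   parcellation; 11 parcels covering VTC itself are excluded *after*
   normalization (to avoid counting fibers looping back into the seed
   region), leaving a 169-parcel profile per (fROI, session) restricted to
   the fROI's hemisphere.
3. **Classification.** Profiles are embedded by PCA (column-mean centring,
   no scaling; component count chosen at the scree-curve elbow by maximum
   perpendicular distance to the first–last chord). A multinomial softmax
   classifier with leave-one-*subject*-out cross-validation predicts
   cytoarchitectonic area (FG2/FG3/FG4), category preference
   (faces/words/bodies/places), or age group, with winner-take-all label
   assignment and an optional balanced-resampling training variant
   (200 draws per label, with replacement).
4. **Eccentricity bands.** The subset of streamlines connecting an fROI to
   early visual cortex (EVC) is split over three eccentricity bands
   (0–5°, 5–10°, 10–20°) by the nearest labeled band vertex of the non-seed
   endpoint; the central-band percentage is analysed with a three-way
   factorial OLS (cytoarchitecture × category × age group, sequential
   type-I sums of squares in that order), paired post-hoc t tests within
   cytoarchitectonic areas (Bonferroni), and random-intercept mixed models
   of `percentage ~ log10(age) + (1 | subject)`.
5. **Development.** Per-parcel simple regressions of endpoint density on
   log10(age in days) give developmental slope maps; a long-form OLS tests
   the age × parcel interaction. Slope similarity between fROI pairs is
   estimated over 1000 bootstrap iterations, each refitting all slopes on
   75% of the profiles (66 of 88; sampled *without* replacement), then
   modelling Fisher-z-transformed pairwise Pearson correlations on
   same-category and same-cytoarchitecture indicators.

All statistics flow through a small shared core (`ols_fit`,
`sequential_anova`, `t_test_d`, `binomial_logit`, `fisher_z`, `bonferroni`)
backed by base R's pivoted-QR `lm`, `glm`, and `t.test`; the multinomial
classifier is `nnet::multinom` (with a small ridge, `decay = 1e-6`, so that
fits remain defined on separable clusters) and the mixed model is
`lmerTest::lmer` (REML, Satterthwaite degrees of freedom).

# The synthetic cohort

Real infant/adult dMRI is not redistributable at the per-session level, so
the package ships a generator that emulates the study conditions and gives
every downstream stage a testable input.

**Sessions.** 88 sessions by default: 23 newborn (28.6 ± 10.2 days),
23 three-month (106.9 ± 19.3 d), 21 six-month (189.0 ± 15.8 d) and 21 adult
(28.21 ± 5.51 years, converted at 365.25 d/yr), truncated to the group bins
(<60, 60–150, 150–250, >6000 days). 42 infant subjects, 21 longitudinal
(4 with three timepoints, 17 with two, allocated near-evenly over the three
group pairs); tiny cohorts degrade to cross-sectional by proportional
(floored) scaling. Each session draws a simulated dMRI outlier-volume
fraction (infants 0.45% ± 0.43%, adults 0.29% ± 0.10%, folded at zero); the
QC filter excludes sessions strictly above 5%.

**Mesh.** A flat 4-mm grid per hemisphere tiled into 180 square parcels.
Parcels 1–11 are flagged excluded and house the fROIs (seed regions sit
inside the excluded VTC block, exactly why those parcels are excluded from
profiles); parcels 12–14 are the three EVC eccentricity bands. Six fROIs on
the left (pFus-faces and pOTS-words in FG2; CoS-places in FG3; mFus-faces,
OTS-bodies and mOTS-words in FG4) and the four non-word fROIs on the right.
Flat geometry with +z normals is deliberate: every downstream operation
consumes only endpoint positions and labels, so realistic folding would add
cost without exercising any additional code path.

**Planted structure.** For each (cytoarchitecture, category) pair the
generator builds a probability vector over retained parcels:

* 25 *hub* parcels per cytoarchitectonic area (weight 8 vs floor 1) — the
  dominant effect;
* a multiplicative category tilt (×1.5 on 10 parcels per category) — a
  weaker effect;
* an age drift: densities scale as `1 + amp · s · (log10(age) − c0)` with
  `amp = 0.12`/log10-day, reference `c0 = 2.7` (≈500 days), and drift
  pattern `s` shared within a cytoarchitectonic area (correlation 0.9
  between fROIs of the same area, independent across areas), weighted-centred
  so total mass is conserved — the weakest effect.

This ordering (cytoarchitecture > category > age) is asserted on the
generated means by `planted_separation()` and is what the classification
stack must recover. A fraction 0.18 of each sub-bundle reaches EVC,
distributed over the bands per area (FG2: 63.6/9.8/26.6%; FG3:
26.6/33.4/40.0%; FG4: 44.0/24.0/32.0% central/mid/far), with per-fROI
central-band offsets (pFus-faces +5, pOTS-words −5 percentage points),
central-band age slopes (FG4 fROIs −2.75, pOTS-words +3.95 points per
log10-day), a per-subject random intercept (SD 3 points) and session noise
(SD 5 points). A fraction 0.05 loops back to the seed parcel, exercising
the exclusion rule. Per-session, per-parcel lognormal density noise
(σ = 0.25) plus multinomial sampling of 2000 streamlines per fROI provide
realistic between-session variability. Band proportions and their slopes,
the cohort layout, and the noise scales were fixed once from the magnitudes
the study design reports; a single pilot run confirmed the planted ordering
before the defaults were frozen.

Because only endpoints matter, streamlines are minimal 3-point jittered
polylines (jitter ±0.75 mm, below half the vertex spacing so endpoints stay
attached to their intended vertex). Every random stage takes an explicit
seed; identical (config, seed) reproduce bit-identical cohorts, meshes,
tractograms and pipeline outputs.

**What the generator does not emulate.** Curved anatomy and fiber geometry,
partial-volume and tracking biases, cross-hemispheric connections, spatially
correlated (rather than parcel-independent) noise, and registration error.
Passing tests therefore demonstrate that the *analysis machinery* is correct
and well-calibrated at realistic effect sizes and sample sizes — not that
the pipeline is robust to tractography artefacts.

# Numerical choices

* **Tie-breaking** is deterministic everywhere: nearest-vertex ties go to
  the lowest vertex index (hence the lowest band), winner-take-all
  probability ties to the first label in canonical order, scree-elbow ties
  to the smaller component count.
* **Radius comparisons are inclusive** (≤ 3 mm); the radius and the
  vertex-assignment drop radius are configurable and default to the same
  3 mm.
* **Aliasing.** Rank-deficient designs (place-selectivity exists only in
  FG3) are handled by pivoted QR, keeping the first-come column. On the
  left-hemisphere factorial replica this forces the term df pattern
  (2, 2, 3, 1, 6, 6, 3) with residual df 504 — a structural consequence of
  the fROI-to-area assignment the tests assert.
* **Profiles are not renormalized after parcel exclusion** by default (the
  density is normalized on the whole surface first); a `renormalize` flag
  exposes the alternative, since either convention is defensible.
* **PCA is fitted once on the full profile matrix** before the
  leave-one-subject-out loop (components are a fixed feature basis); the
  leakage-free per-fold refit is available behind `refit_pca_per_fold` and
  gives the same conclusions on the default cohort.
* **Chance level** is 1/#classes (1/3 for cytoarchitecture, 1/4 for
  category and age).
* **Mixed-model boundary fits** (between-subject variance → 0) collapse to
  the OLS solution and are flagged rather than erroring.
* **Degenerate t tests** (zero sample SD) return explicit sentinels instead
  of NaN: t = 0, p = 1 when the mean equals the null value, t = ±Inf, p = 0
  when it does not (the limit of perfectly consistent evidence, e.g. a task
  classified at 100% in every session).
* **Bootstrap subsamples** are drawn without replacement (75% of profiles);
  iterations are *paired* across fROIs (iteration k uses the same session
  subsample for every fROI) so per-iteration correlations compare like with
  like; an unpaired mode is available by passing per-fROI index matrices.
  Degenerate subsamples (a single unique age) are redrawn and counted.
* **Fisher z** clips |r| at 1 − 1e-12 so boundary correlations stay finite.

# Validation design

The test suite follows a dual-route pattern: every geometric or statistical
operation is checked against an independent oracle on small instances
(brute-force all-pairs distances for the radial search and nearest-vertex
assignment, grouped sums for parcel aggregation, eigen-decomposition for
PCA variance, exhaustive perpendicular distance for the elbow, binary
`glm` for the two-class softmax, nested-model RSS differences for the
sequential ANOVA, a REML criterion grid for the mixed model), plus
property-style invariants (selection monotone in radius, densities summing
to 1, confusion rows summing to 100, permutation invariance) and
full-cohort recovery runs at the default problem sizes (88 sessions,
2000 streamlines per fROI-session, 1000 bootstrap iterations; the
calibration suites use reduced problem sizes — e.g. 500-replicate null
simulations of the factorial design at 3 sessions per cell — chosen so the
whole suite stays desk-scale).

One null check deserves a note. The slope-similarity model is fitted, as in
the headline analysis, across all pair × bootstrap-iteration rows
(15 × 1000 at defaults). Bootstrap iterations of one pair are resamples of
a single dataset, not independent draws, so under a true null the row-level
t statistic is strongly anticonservative. The null-calibration test
therefore (a) generates data with no hub or category structure, making all
fROI pairs exchangeable under the null, and (b) tests the
same-cytoarchitecture coefficient on pair-level mean correlations
(15 observations). The positive direction — planted parallel development
within an area is detected, with the same-cytoarchitecture coefficient
positive and larger than the same-category one — is asserted on the full
default generator.

# Known limitations

* The mixed-model degrees of freedom are Satterthwaite approximations;
  fractional dfs will not reproduce another environment's values exactly.
* The similarity model's row-level standard errors inherit the bootstrap
  clustering described above; treat its CIs as descriptive, as the
  pair-level summary is the calibrated quantity.
* The track-file reader supports Float32 little/big-endian data, the
  layout produced by standard tractography tools; other datatypes raise a
  named format error rather than being converted.
* Classification with very small cohorts can leave a label unrepresented in
  a training fold; this is a hard, named error rather than a silent skip.
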