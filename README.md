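# vtcwm

White-matter connectivity profiles of human ventral temporal cortex (VTC),
from streamline tractography to inference.

Category-selective regions in VTC (face-, word-, body- and place-selective
fROIs) sit inside cytoarchitectonic areas FG2–FG4 of the fusiform gyrus. A
central question in visual neuroscience is which feature organizes their
white-matter connections — category, cytoarchitecture, or retinotopic
eccentricity — and how those connections change from infancy to adulthood.
`vtcwm` implements the full analysis chain used to answer it:

- **Sub-bundle extraction** — select the streamlines of a tractogram whose
  terminal points fall within a 3 mm radial search of a surface fROI
  projected to the gray/white interface.
- **Connectivity profiles** — map both terminal points of each selected
  streamline to the nearest surface vertex, normalize to an endpoint-density
  map (sums to 1), and aggregate over a 180-parcel/hemisphere cortical
  parcellation with 11 seed-region (VTC) parcels excluded, giving a
  169-parcel profile per (fROI, session).
- **Classification** — PCA (elbow-selected components) plus
  leave-one-subject-out multinomial logistic regression with winner-take-all,
  predicting cytoarchitecture, category, or age group from profiles;
  balanced-resampling training variant; binomial-regression comparison of
  tasks; one-sample *t* tests of session accuracies against chance
  (`acc ~ chance`, Cohen's *d*).
- **Eccentricity bands** — percentage of an fROI's early-visual-cortex
  streamlines terminating in the 0–5°, 5–10° and 10–20° bands; factorial
  model `central% ~ cytoarchitecture × category × age group` (sequential SS,
  η²), paired post-hoc *t* tests (Bonferroni), and random-intercept mixed
  models `central% ~ log10(age) + (1 | subject)` (REML, Satterthwaite df).
- **Development** — per-parcel slopes of endpoint density on
  log10(age in days) (`density ~ log10(age)`, and the global
  `density ~ log10(age) × parcel` interaction test); 1000-iteration bootstrap
  of slopes on 75% subsamples; pairwise slope correlations modelled as
  `FisherZ(r) ~ same_category + same_cytoarchitecture`.
- **Synthetic cohort generator** — session tables (88 sessions in four age
  groups with longitudinal infants), labeled meshes (parcels, fROIs,
  eccentricity bands) and tractograms with planted statistical structure, so
  the whole pipeline runs and is validated without MRI data. MRtrix
  track-file (`.tck`) and ASCII PLY I/O are included.

## Worked example

A reduced synthetic cohort (30 sessions, 500 streamlines per fROI-session)
runs in about a minute:

```r
library(vtcwm)

cfg <- run_config(seed = 1,
                  n_streamlines_per_froi = 500,
                  n_iter = 100,
                  cohort = cohort_config(counts = c(newborn = 8, "3mo" = 8,
                                                    "6mo" = 7, adult = 7)))
res <- run_pipeline(cfg, progress = FALSE)

print(res$profiles)
print(res$pca)
for (r in res$classification) print(r)
```

```
profile_matrix: 300 profiles x 169 parcels ( 30 sessions, 10 fROIs )
PCA: 169 components; elbow at 5 ( 70.9 % variance )
LOO classification of cytoarchitecture: mean accuracy 100.0% +/- 0.0% (chance 33.3%)
LOO classification of category: mean accuracy 67.7% +/- 11.7% (chance 25.0%)
LOO classification of age_group: mean accuracy 16.7% +/- 15.8% (chance 25.0%)
```

Each of the 300 rows is one fROI's endpoint-density fingerprint in one
session. Cytoarchitectonic area is read off the profiles essentially
perfectly, category preference is decodable but imperfect, and at this
reduced cohort size age group is at chance — the planted effect hierarchy
(cytoarchitecture > category > age). The eccentricity and development stages
print the corresponding group-level statistics:

```
factorial: cytoarchitecture F(2,156) = 194.7, eta^2 = 0.67
central-band means: FG2 62.3%, FG3 25.7%, FG4 43.7%
slope similarity: same-cytoarchitecture coefficient 0.48 (z units)
```

FG2 regions connect mostly to the central 5° of early visual cortex, the
FG3 place region mostly to the periphery, and developmental slope maps are
far more similar for fROIs within the same cytoarchitectonic area than for
fROIs sharing only a preferred category.

At the full default scale (`run_config(seed = ...)`: 88 sessions, 2000
streamlines per fROI-session, 1000 bootstrap iterations) the same pipeline
yields 880 profiles, a factorial model with residual df 504, session-level
accuracy *t* tests with df 87, and a 15 000-row slope-similarity model with
residual df 14 997. `run_pipeline(cfg, out_dir = "...")` writes every stage
as TSV/JSON plus a manifest of file hashes; reruns with the same config are
bit-identical.

See the methods vignette (`vignettes/methods.Rmd`) for the model
definitions, generator design, numerical conventions and validation
strategy.

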