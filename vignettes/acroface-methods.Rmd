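---
title: "Craniofacial morphometrics and discriminant screening for acromegaly: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Craniofacial morphometrics and discriminant screening for acromegaly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acroface)
```

## The scientific problem

Acromegaly — chronic growth-hormone hypersecretion, almost always from a
pituitary somatotroph adenoma — remodels the face slowly enough that neither
patients nor non-specialist physicians notice until the disease is advanced.
Quantitative 3D facial morphometry offers a route to earlier detection: a
published matched case-control study of 62 patients and 62 controls (34/34
male, 28/28 female) measured 58 craniofacial parameters per subject from 3D
surface scans, screened them univariately for disease and sex effects, and
showed that a linear discriminant over the full parameter set predicts
disease state out-of-sample with high accuracy.

`acroface` implements that full analysis as a reusable, testable pipeline:
landmark geometry and Frankfort alignment, the 58-parameter measurement
catalog, the univariate screening battery, a from-first-principles linear
discriminant analysis (LDA) with leave-one-out cross-validation (LOOCV) and
a label-permutation null, and a seedable synthetic-cohort generator. The raw
scans of the study are not deposited ("available on request"), so the
generator — driven by the packaged per-cell summary statistics — is the
package's stand-in data source, and every empirical claim the package makes
is computed by its own tests and drivers.

## Geometry: frame, alignment, reference planes

All coordinates are millimetres in a right-handed frame; after alignment
the convention is **+x subject-left, +y superior, +z anterior**, origin at
the tragion midpoint.

**Frankfort Horizontal (FH) alignment.** Classic FH runs through porion and
orbitale on bone. On the soft-tissue landmark set the closest proxies are
the left/right tragion (`tr`) and the left/right inferior orbital groove
(`or`), so `align_frankfort()` takes the least-squares plane through those
four points as horizontal, the tragion axis as lateral, and resolves the
two sign ambiguities by requiring the facial landmark centroid to lie
anterior of the ear axis. The transform is rigid: every pairwise distance is
preserved to 1e-9 mm (tested), and aligning an aligned scan is the identity.

**Reference planes.** The midsagittal plane is the vertical plane minimizing
the summed squared distances of the midline landmarks (exact for a
symmetric face); the esthetic plane is the Ricketts E-line
(pronasale-pogonion) extruded vertically and made perpendicular to the
midsagittal plane, signed anterior-positive so protruding lips score
positive; the true vertical line (TVL) is the vertical plane through
subnasale, anterior-positive; the transglabellar / midfacial / transverse
nasal planes are horizontal planes through glabella, the infraorbital
midpoint, and subnasale; and the two "plumb" planes through the preaurale
points, perpendicular to the anterior axis, clip the facial cross-sections
— a line cannot clip a surface, so the published plumb *lines* are realized
as clipping half-spaces.

**Mesh sectioning.** A triangle mesh is cut by a plane by intersecting every
crossing triangle and chaining the resulting segments into maximal
polylines; endpoints are matched on a grid of 1e-6 times the bounding-box
diagonal (resolution-relative, so refinement does not break chaining).
Vertices that fall numerically on the plane would make the cut topology
unstable, so the plane is offset by a deterministic 1e-9 of the bounding
box instead — a bias orders of magnitude below measurement precision.
Section arc lengths on spheres and cylinders converge to the closed forms
(tested at 1%, with the expected second-order behavior under refinement).
The three semi-perimeters (PTGP, PMFP, PTNP) keep the most anterior section
component and clip it at the preaurale plumb planes, side-resolved.

## The 58-parameter catalog

The catalog is **data, not code** (`inst/extdata/catalog.json`): each entry
declares an acronym, a kind (linear, axis depth, curve/chain, angle,
vector angle, index, triangle index, tragion depth, plane distance,
difference, or cross-section semi-perimeter), operands, and units. The
study's supplementary operand definitions are not public, so the defaults
follow standard soft-tissue anthropometry — e.g. morphological face height
`n–gn`, face breadth `zy–zy`, intercanthal index `100·ICW/BnW`,
endocanthal-alar index `100·ICW/NW` — chosen once, before any testing, so
that the published male-control means are approximately reproduced (44.40
vs printed 44.41 for the intercanthal index). If the true definitions
surface, a new catalog file drops in without touching the engine. Bilateral
operands are evaluated per side and averaged unless the measurement is
inherently bilateral (a width). Curve entries use the mesh section path
between their landmarks when a mesh is present (provenance recorded), else
the straight landmark chain; without a mesh exactly the three
semi-perimeters are missing, with per-entry diagnostics rather than errors.

Evaluation is in catalog order, which is a topological order of the
measurement-to-measurement dependencies (validated at load). Invariants
under rigid motion (1e-6), uniform scaling (mm entries scale, angles and
indices fixed) and mirroring with left/right relabeling are tested over the
whole catalog.

## The univariate battery

Per variable: per-cell means and SDs; a classic mean-centered Levene check
(Brown-Forsythe by flag; a perfectly homogeneous degenerate sample returns
W = 0, p = 1); a two-way sex-by-disease ANOVA; and within-sex pooled-variance
t-tests. Choices where the study is silent:

- **Sums of squares**: the sexes are unbalanced (34 vs 28 pairs), so Type II
  is the default (each main effect adjusted for the other; interaction
  last), with Type I and III available. The implementation is explicit
  nested-model residual comparisons on a sum-coded design, which is exact,
  fast, and well-defined even at zero residual variance; it is cross-checked
  against an established general implementation in the test suite.
- **t-test flavor**: Student pooled-variance, because variance homogeneity
  is screened by the Levene step; Welch by flag.
- **Significance**: strict `p < 0.05/58` (the exact rational threshold,
  8.62e-4 to three significant figures), two-sided throughout. These
  conventions reproduce all six published significance counts
  (38/26/21/33/14/12) from the packaged p-value table.
- **Direction**: patient-minus-control pooled means weighted by cell size;
  this reproduces the published 32 higher / 6 lower split, the six
  lower-in-patients variables being the mandibulo-facial, intercanthal,
  nasal-length and endocanthal-alar indices and the nasofrontal and
  nasomental angles.

The published post-hoc p-values are **not** recomputable from the printed
summaries: pooled-variance t on the printed means/SDs/ns gives |t| ≈ 7.90
(df 66, p ≈ 3e-11) for male face height where the table prints 6.48e-08.
Whether a paired test or some adjustment produced the printed values cannot
be determined from the text, so the printed p-values are used only as
literal inputs to the count-based summaries, never as oracles.

## The discriminant stage

For each sex separately: features are z-scored, and the two-class LDA
weight solves `(S_pooled + λI) w = μ_patient − μ_control` with the decision
threshold midway between the projected class means plus the log prior
ratio. Design choices:

- **Priors** equal by default (the cells are balanced within sex);
  proportional by flag.
- **Ridge** `λ` defaults to 1e-6 times the mean diagonal of the pooled
  covariance — 58 features against 55–67 training rows is numerically
  fragile — and `λ = 0` is accepted whenever the covariance is full rank.
  With `λ = 0` and equal priors the predictions coincide label-for-label
  with an established reference implementation (tested on 100 random
  instances).
- **LOOCV** refits both the standardization and the LDA on each fold's
  n−1 subjects; the held-out subject never influences its own fold (a
  leakage test perturbs it and asserts the fold model is unchanged).
  Internally the per-fold statistics are exact rank-one downdates of
  whole-sample statistics — algebraically identical to refitting (asserted
  against a naive refit) but fast enough to sit inside the permutation
  loop. Whether the original study standardized inside or across folds is
  unstated; within-fold is the default, whole-sample by flag.
- **Permutation null**: labels are uniformly reshuffled, the full LOOCV is
  rerun, and `p = (1 + #{null ≥ observed}) / (B + 1)` (the add-one
  estimator; the study reports only bounds like "< 0.0001"). The study-scale
  `B` is 10,000 (the default); the analysis drivers and tests use `B = 999`
  as a desk-scale setting. Under label-independent data the mean null LOOCV
  accuracy sits at the chance level 0.5 within Monte-Carlo error, and the
  permutation p-value is super-uniform — both are asserted by the test
  suite at `n = 60`, 10 features, `B = 999`.
- **Loadings** come from an LDA on the z-scored *full* sample (mirroring the
  study's choice); features are ranked by absolute loading with a
  lexicographic tie-break. **Box's M** (chi-square approximation,
  df `p(p+1)/2` for two groups) screens covariance homogeneity and refuses
  designs with `n ≤ p` per class rather than returning an untrustworthy
  statistic; on cohorts generated from the packaged summary it often
  *rejects* homogeneity, correctly, because the published per-cell SDs
  themselves differ between patients and controls.
- Ties at the decision boundary go to "control" — determinism over elegance.

## The synthetic generator

**Feature level.** Each sex-by-group cell is multivariate normal with the
packaged published means and SDs and exchangeable inter-feature correlation
`ρ = 0.3` by default (facial measurements are mutually correlated;
independence would make the discriminant problem unrealistically easy; ρ is
a free parameter and no packaged result depends on its value). Gaussian
cells are the minimal assumption consistent with the t/ANOVA battery; no
truncation is applied because every packaged SD is small relative to its
mean. Draws are seed-deterministic, and the empirical moments converge to
the specification at the usual root-n rate (tested at n = 10,000 per cell).

**Landmark level.** A bilaterally symmetric template face (35 landmarks +
preaurale, plausible adult geometry, absolute values arbitrary — every
recovery analysis is differential) is deformed by additive displacement
fields: a male-sex field (global enlargement) and a disease field emulating
the published direction summary (nose widening and elevation, vermilion
thickening and eversion, mandible enlargement), plus i.i.d. isotropic
landmark noise (default 0.5 mm, a typical manual landmarking repeatability —
the imaging hardware itself is quoted at 0.001 mm) and a random rigid
motion per subject so the alignment stage does real work. The optional head
mesh is an ellipsoid radially warped through the template landmarks by a
regularized spherical Gaussian RBF (σ = 0.12 rad, ridge 1e-3, landmark
residuals < 0.1 mm — parameters chosen by conditioning, not fit to data)
and deformed consistently with the landmarks via Gaussian-kernel
interpolation of the displacement fields.

**What passing tests do and do not show.** The generator reproduces the
study's *statistical* structure — cell moments, correlation scale, cohort
sizes, landmark noise — not real faces: no photorealistic surface detail,
no asymmetry, no growth trajectories, no measurement-specific error
structure. Pipeline correctness (alignment, measurement, inference
machinery, error control, recovery of planted effects) transfers to real
data; the specific accuracy numbers obtained on synthetic cohorts do not.

## Problem sizes and numerical conventions

The test suite and drivers use desk-scale sizes chosen as the package's
own defaults: permutation checks at `B = 999` (one fixed cohort of n = 60,
10 features) and `B = 39–49` across 60 small replicate datasets for
super-uniformity; the landmark-effect recovery study at 200 replicates of
the full 124-subject cohort (noise 0.5 mm, a planted nose-widening /
lip-displacement field), asserting ≥ 95% recovery of the displaced
distances and a family-wise false-positive count within the upper 0.999
binomial band of the 0.05 guarantee. Segment chaining uses the
1e-6-relative tolerance above; the LDA linear solves are plain dense
`solve` on 58×58 or smaller systems; all randomized procedures take
explicit seeds and restore the caller's RNG state.

## Known limitations

- The measurement operand defaults stand in for unavailable supplementary
  definitions; absolute agreement of individual measurements with the
  study's values is therefore not guaranteed (and not claimed) — the
  catalog file is the single place to fix them.
- The published post-hoc p-values cannot be reproduced from the printed
  summaries (see above); counts built on them are reproduced exactly, but
  the underlying test remains uncertain.
- The published LOOCV accuracies (92.86% female, 75% male) require the raw
  scans and are reproduced here only as confusion-matrix arithmetic; the
  synthetic cohorts yield accuracies of the same order but not the same
  numbers, and with unknowable inter-feature correlation they cannot
  adjudicate fold-wise versus global standardization or prior choice.
- The matched 1:1 design is analyzed, as in the study, with independent
  two-sample machinery; no paired modeling is attempted.
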