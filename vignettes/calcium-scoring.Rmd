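---
title: "Automated coronary calcium scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated coronary calcium scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciscan)
```

## The problem

Coronary artery calcification (CAC) is a strong marker of cardiovascular
risk, conventionally quantified on CT as the Agatston score and grouped into
five risk strata (0, 1–10, 11–100, 101–400, >400). Lung-cancer screening
produces large numbers of low-dose, non-ECG-gated chest CTs on which manual
CAC scoring is slow and, because of cardiac motion and noise, error-prone.
`calciscan` implements a fully automated scoring pipeline for such scans —
candidate extraction, atlas/texture-feature classification, Agatston/volume/
count quantification, risk stratification — together with the complete
agreement-and-reliability statistics suite needed to evaluate any scoring
method against a reference standard, and a seeded synthetic phantom
generator that makes the whole chain testable end to end.

## The pipeline

**Extraction.** Calcified tissue attenuates above 130 HU, so candidates are
the maximal connected components of the voxel set `HU >= 130`
(threshold inclusive, the Agatston convention) under a 3D neighbourhood.
The default connectivity is 26 (faces, edges and corners); 6 and 18 are
available. Components are ordered deterministically by the raster position
of their first voxel. Nothing is excluded at this stage: bone and aortic
calcium survive to the classifier, and oversize components are only flagged.

**Features.** Each candidate is described by

* its volume in mm³ (size),
* the a-priori coronary-calcium probability at its centroid, read from a
  spatial atlas, plus its normalised centroid coordinates (space), and
* Gaussian texture features at scales 1, 2 and 4 mm: smoothed intensity,
  gradient magnitude and Laplacian, with derivatives taken in mm units so
  the features are independent of the anisotropic voxel grid (texture).

The atlas is the voxelwise mean of spatially normalised binary coronary
masks of training scans, Gaussian-smoothed and clipped to [0, 1]. Spatial
normalisation is a deliberately simple moment-matching affine (centroid and
per-axis SD of a thoracic soft-tissue mask): the contract only requires a
transform into a common frame in which homologous territories roughly
align, and at phantom scale this is sufficient. The default scale set
{1, 2, 4} mm spans the lesion radii the phantom generates and is
configurable.

**Classification.** Candidates are classified coronary vs non-coronary by a
two-stage supervised system: a k-nearest-neighbour stage (default k = 15,
z-scored features using training statistics stored in the model) produces a
posterior; outside the uncertainty band (default 0.3–0.7) the kNN majority
decides, inside it an RBF support vector machine trained on the same data
decides. The two-stage arrangement is one reasonable combination of the two
named classifiers; both degenerate single-stage modes are reachable
(`band = c(0.5, 0.5)` is pure kNN, `band = c(0, 1)` pure SVM), and no claim
is made that these hyperparameters reproduce any particular historical
implementation — k, the kernel, the band and the scale set are all
configuration with documented defaults.

**Scoring.** Each coronary lesion contributes the per-slice sum of
`area (mm²) × weight(max HU)`, with weights 1–4 over the HU bins
[130, 200), [200, 300), [300, 400), [400, ∞); slices with area below 1 mm²
(the classic speck filter) contribute nothing. Because the Agatston
definition assumes contiguous 3 mm slices while screening reconstructions
here are 3.1 mm slices at a 1.4 mm increment, the per-scan sum is
multiplied by `thickness / 3` (default 3.1/3 ≈ 1.033). Every reconstructed
slice on the stored 1.4 mm grid contributes — no de-overlap correction is
applied, mirroring scoring on the stored reconstruction. Calcium volume
(voxel count × voxel volume) and lesion count are never
thickness-normalised. Fractional scores are kept unrounded; strata use
half-open boundaries (a score of exactly 400 is "101–400"), a convention
required once automated scores are fractional.

## The phantom

The generator emulates the geometry and first-order statistics of a
non-gated low-dose chest CT: a 72 × 72 × 40 grid at 0.66 × 0.66 × 1.4 mm
(3.1 mm thickness as metadata), a flat 30 HU soft-tissue background,
additive Gaussian noise, and optional 1D Gaussian motion blur along the
anterior-posterior axis — a one-parameter stand-in for cardiac motion
unsharpness. Lesions are Gaussian-profile spheres whose profile crosses
130 HU exactly at the nominal radius, so the ground-truth mask is the
rasterised analytic sphere and an exact volume oracle exists. Territories
are fixed geometric boxes (coronary vs aortic), not anatomy. Under the
default study conditions each phantom carries 0–4 coronary lesions (radius
1.5–4 mm, peak 180–700 HU) and 0–2 aortic distractors; noise sd 20 HU is
used for the end-to-end evaluation. The generator does *not* model beam
hardening, photon statistics, scanner dialects, or real anatomy — passing
tests demonstrate that the pipeline's logic is correct and that the
detector can exploit spatial and intensity structure, not that it would
reach the same operating point on patient scans. In particular the
published real-data ICCs and medians depend on patient data and are not
reproducible here; the end-to-end acceptance surface is per-candidate
accuracy and scan-level category agreement on held-out phantoms.

The paper of record for the evaluated statistics gives no noise magnitude
for its low-dose protocol; 20 HU is a fixed choice of this package's test
conditions, not a claim about any trial's scans.

## The agreement suite

Given a reference and an automated score set the package computes:

* **Proportion of agreement** (trace over total of the 5 × 5 category
  matrix) and the **category-shift histogram**, including the count shifted
  by more than one stratum and the **false-negative zeros** (automated "0"
  against a nonzero reference).
* **Linearly weighted kappa**, `1 − Σv·o / Σv·e` with `v_ij = |i−j|/(k−1)`.
* **ICC** from the two-way mean squares: consistency ICC(3,1) for the
  "two-way mixed" reference-vs-automated comparison (the default), absolute
  agreement ICC(2,1) for the "two-way random" multi-rater case. The model
  family names leave the form open; single-measure consistency is the
  default and both forms are exported.
* **Kendall's W** with mid-rank ties and the standard tie correction.
* **QCD** `(Q3−Q1)/(Q3+Q1)` with type-7 (linear-interpolation) quartiles —
  the common statistics-package default; the choice affects the second
  decimal at most.
* **Bland-Altman with non-uniform limits**: calcium-score error grows with
  the score, so `|ref − auto|` is regressed on `sqrt(mean)` and the 95%
  limits at mean x are `±(a + b√x) · 1.96·√(π/2)`. The multiplier converts
  the predicted mean absolute difference of a half-normal into the ±1.96 sd
  band (`E|X| = σ√(2/π)`). Limits are zero-centred — the reference formulas
  carry no offset term — and a negative fitted absolute difference (the
  intercept can be negative) is clipped to 0 before scaling. Point
  estimates only; no standard errors or p-values are computed anywhere in
  the suite.

The bundled `screening_shift_matrix()` — a published 5 × 5 cross-tabulation
from 1749 screening scans — exercises the categorical block end to end.

## Numerical choices and degenerate inputs

Gaussian filtering is separable, spacing-aware, truncated at 3σ and
renormalised, with replicate padding (constant volumes are exactly
invariant). Interpolation is trilinear with out-of-frame queries returning
0 by contract. Connected-component labeling is compiled (Rcpp) iterative
flood fill; a brute-force R flood fill serves as its oracle in the tests.
Degenerate statistical inputs fail loudly rather than silently: single-cell
confusion matrices, zero-variance ICC tables, all-constant ratings and
constant-mean Bland-Altman inputs all raise errors. kNN vote ties cannot
occur with the odd default k; distance ties are included deterministically.
Classifier persistence stores the standardised training data and refits the
SVM stage deterministically on load, which round-trips decisions exactly
without serialising libsvm internals.

## Problem sizes

The test suite and the acceptance script use 50 training and 50 held-out
phantoms for the end-to-end evaluation, 10⁴ simulated pairs for the
Bland-Altman coverage property, 10⁵ pairs for the kappa-recovery property,
and 100–200 random tables for the labeling and ICC oracle equivalences —
sizes at which the checked estimates are stable to well within their
asserted tolerances.

## Known limitations

Geometric territory boxes stand in for coronary anatomy, so per-artery
attribution is out of scope; stents, metal artifacts and DICOM ingestion
are not modelled; kappa/ICC interval estimates are not provided; and the
thickness-normalisation question for overlapping reconstructions is
resolved by a documented configurable default rather than a claim about any
particular scanner's software.
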