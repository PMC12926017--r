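---
title: "Shape-based body condition scoring from depth images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based body condition scoring from depth images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcs3d)
```

## The problem

Body condition score (BCS) grades the subcutaneous fat reserves of cattle,
here on the French 0–5 grid. It is normally assigned by a trained technician
by eye and palpation, about once a month. In gestating heifers the changes of
interest are small — a tenth of a point over weeks — which is below what
monthly manual scoring can resolve. An overhead depth camera scores an animal
every time it walks under the rig, so weekly (or denser) trajectories become
available, provided the depth image can be turned into a score automatically.

`bcs3d` implements that chain: depth acquisition geometry, automatic
detection of the four pelvic landmarks, landmark-based normalization of the
dorsal *hips-to-pins* surface, a PCA-plus-regression shape model that maps a
normalized surface to a BCS, and the longitudinal layer (record filtering,
LOESS smoothing, device-vs-manual comparison, herd summaries). Because no
depth imagery of the study animals is released, the package also ships a
synthetic scene generator rich enough to exercise — and falsify — every stage.

## The scoring model

A single depth frame is back-projected through the pinhole model to a point
cloud (`depthToPointCloud()`). Four landmarks anchor everything: the tops of
the left and right ischia (pin bones) and the bases of the left and right
sacra. From them `computeFrame()` builds the canonical animal frame — origin
at the landmark centroid, x from left to right ischium, y toward the sacrum
midpoint (orthogonalized), z dorsal — and `extractROI()` resamples the
canonical-frame cloud over the landmark bounding box (expanded 10% per side)
onto a fixed 150 × 150 grid by inverse-distance weighting (k = 8 neighbours,
radius 25 mm, inverse squared distance). The grid is size-relative: a wider
animal is sampled over a wider rectangle, and the physical extent is kept in
`scaleRecord` rather than being normalized away, so no size information is
silently destroyed.

Missing cells (sensor dropout, occlusion) are filled by a discrete harmonic
fill — Jacobi iteration of the 4-neighbour average to a 10^-6 mm tolerance —
with the original validity mask kept for audit (`imputeSurface()`). Surfaces
with less than 60% valid support are rejected rather than imputed.

The shape model itself (`fitShapeModel()`) is deliberately plain:
principal-component analysis of the flattened grids (components from the
covariance spectrum, signs fixed so each component's largest-magnitude
loading is positive, which makes training bit-reproducible), followed by
ordinary least squares of BCS on the retained PCA coordinates. The retained
dimension is the smallest explaining 95% of variance, capped at 20 and at
n − 2 so the regression stays overdetermined. Predictions are clipped to
[0, 5] at the API boundary. OLS rather than a penalized fit is a deliberate
choice: the coordinates are orthogonal by construction and the cap keeps the
design well-conditioned; a ridge penalty would only obscure the comparison
with the plain multiple-regression formulation the method descends from.

## Landmark detection

The landmark detector is fully geometric, with no learned parts:

1. **Sagittal plane** by a robust symmetry fit: grid search (±25°, refined to
   a parabolic sub-step) over plane orientations through the cloud centroid,
   minimizing the mean left–right height difference of a coarse raster.
   Rasters are anchored at the centroid, which makes the whole detector
   equivariant under the rigid transforms it is specified for (yaw within
   ±15° of the rig axis).
2. **Tail-head depression**: most prominent dip of the quadratic-detrended
   midline height profile; its position also decides which end of the body
   axis is posterior.
3. **Ischia**: per lateral half, local maxima of a quadratically detrended
   height raster in the posterior band; the most posterior candidate whose
   prominence exceeds the threshold (default 3 mm ≈ one sensor noise sd)
   wins. Candidates must be interior cells (a genuine bump has a full
   8-neighbourhood) and reach 60% of the strongest candidate's prominence —
   both guards against isolated noise maxima.
4. **Sacrum bases**: per half, the sacral prominence peak is located in the
   anterior band, then the landmark is placed at the inflection (zero
   crossing of the second difference) of a finely binned longitudinal
   profile, walking from the peak toward the tail head. "Base of the sacrum"
   is geometrically ambiguous; this inflection reading is our documented
   operationalization, not a claim about the commercial device.

Peaks are refined to sub-cell positions by 1-D parabolic interpolation, and
heights are read from raw points near the peak, so detections are continuous
in the input. When no prominence clears the threshold the best-guess location
is still returned with confidence 0 — a detection-failure *result*, not an
exception — so downstream stages can decide what to do with low-trust frames.

## The synthetic generator

No geometric description of how fattening reshapes a heifer's back exists in
a usable form, so the generator is an explicit, documented stand-in: a smooth
quadric base cap plus Gaussian features — a spinal ridge, two pin bumps (the
ischia), two sacral bumps, two hook bumps and a tail-head depression — each
scaled by one latent fatness parameter. The default BCS-to-geometry map is
affine and strictly decreasing (`defaultFatness()`):
spine 12 − 2.4 b, hook 15 − 3 b, pin 10 − 2 b, tail depression 25 − 5 b (mm),
all exactly zero at BCS 5. The constants are chosen so one BCS point moves at
least one feature by 5 mm, the order of magnitude palpation relies on; they
are not claimed to match real heifers.

Morphology defaults come from the packaged 13-heifer table (hip width 507 mm,
withers height 1376 mm; modelled patch length 450 mm), and `simulateAnimals()`
jitters them per animal with the table's observed spread (sd 25 / 47 / 30 mm).
Two further realism terms matter for what the tests mean:

* **Anatomic variation**: each animal's prominences are multiplied by
  independent log-normal factors (sd 0.08). Without this, BCS would be a
  deterministic function of shape and the evaluation would be trivially
  optimistic; with it, the *best achievable* RMSEP at the study's scale is
  about 0.1 BCS points, so the pipeline is evaluated against a floor.
* **Acquisition nuisances**: body pose (yaw ≤ 10°, tilt ≤ 3°, offsets
  ≤ 40 mm), i.i.d. Gaussian depth noise (default sd 3 mm) and Bernoulli
  pixel dropout (default 5%), applied by `corruptDepth()`.

Every feature is analytic, so the generator doubles as the oracle: landmarks
sit at closed-form positions, the surface has closed-form heights
(`dorsalHeight()`), mirror symmetry is exact, and mean absolute curvature of
the normalized grid decreases strictly with BCS — the property that makes the
PCA-regression identifiable in the first place.

What the generator does **not** emulate: posture variation, head/leg
occlusion, pen fixtures, non-rigid deformation while walking, RGB texture,
and any real covariance structure between features beyond the shared latent
score. Passing tests therefore show that the pipeline recovers scores when
its geometric assumptions hold, at realistic noise; they do not certify field
accuracy on real animals.

## Stereo front end

The rig's depth originates from two-view triangulation. The package includes
the reference pieces — integer block matching by sum of absolute differences
(`findDisparity()`, ties toward the smaller disparity), `z = f·B/d`
triangulation, and bit-exact 16-bit PNG / binary PLY I/O — because they define
the data contract, but the scoring pipeline consumes depth maps directly.
Sub-pixel disparity refinement is a declared non-goal: the accuracy-critical
surface is the shape model, not the stereo stage. Default intrinsics
(fx = fy = 600 px at 640 × 480, baseline 55 mm) are configuration values, not
device claims.

## Longitudinal monitoring

Records (`animal_id`, ISO date, source ∈ {bcs3d, bcsm, bw}, value) pass
through:

* `filterAberrant()` — a record is removed only when it deviates beyond the
  threshold from **both** its date-order neighbours (BCS: > 0.5 points;
  body weight: > 20% relative), endpoints exempt. The both-neighbours reading
  follows the conjunctive phrasing of the rule and spares genuine monotone
  trends; a single pass against original neighbours is provably idempotent.
  By default the rule applies to manual scores and weights only, the sources
  for which it was historically formulated; the device series can be opted in
  via `sources=`.
* `loessSmooth()` — classical LOESS, written out in full: q = ⌈span·n⌉
  nearest neighbours, tricube weights, local polynomial of degree 1 or 2, no
  robustness iterations. Defaults span 0.75, degree 2 (the common plotting
  default for such curves). Every fitted value is checked against an
  independent per-point weighted-least-squares solve in the tests;
  `loessPredict()` evaluates the same estimator off-grid, which is what
  `seriesChange()` uses to report changes and daily rates (g/d for weight)
  between two dates.
* `compareMethods()` — pairs manual and device scores within ±3 days and fits
  the through-origin line (slope = Σxy/Σx²). The reported R² uses the
  *uncentered* sum of squares: a no-intercept model form forces that
  convention, and it is documented here precisely because it is not
  interchangeable with the centred R² of an ordinary regression.
* `summarizeHerd()` — per-column mean and sample (n − 1) SD with pairwise
  missing-value exclusion; rounding is presentation-only.

## Numerical choices and degenerate inputs

* Invalid depth is 0 mm in files with an explicit mask in memory — integer
  formats cannot carry NaN.
* Zero total variance in training yields k = 0 and an intercept-only model;
  components below 10^-12 of the leading eigenvalue are treated as null.
* The PCA spectrum is computed from the n × n Gram matrix (n ≪ 22 500), which
  is exact, deterministic and an order of magnitude faster than a full SVD.
* Local LOESS systems are solved by weighted normal equations after centring
  at the evaluation point; with n ≤ 60 and degree ≤ 2 their conditioning is
  benign, and the oracle agreement requirement is 10^-8.
* Ties in LOESS neighbour selection are broken by abscissa order; ties in
  frame selection by ROI coverage, then earliest timestamp.
* Clouds under 1 000 points, empty ROIs, collinear landmarks and
  sub-threshold valid fractions raise typed errors (`degenerateInput`,
  `degenerateGeometry`, `qualityReject`) rather than propagating NaN.
* One integer run seed drives everything; per-animal and per-stage seeds are
  split by a documented affine counter (`deriveSeed()`), so any stage can be
  re-run in isolation, bit-identically.

## Problem sizes

The shipped evaluation trains on 200 synthetic animals and tests on 100
(`rmsepExperiment()`), the scale at which the OLS sampling error on the
regression coefficients stays well below the anatomic-variation floor; the
seed-stability property repeats the full experiment over ten seeds and
requires the RMSEP spread to stay under 0.1 points. The end-to-end manifest
run (`runPipeline()`) uses a small cohort since it checks wiring and
reproducibility, not accuracy.

## Known limitations

* The generator's BCS-to-geometry constants are invented; conclusions
  transfer to real heifers only insofar as real dorsal shape carries a
  comparable monotone fatness signal.
* The detector assumes a roughly overhead, roughly axis-aligned view (yaw
  within ~15°); it has no occlusion model and is not meant for full-body
  standing scans with head and legs.
* At twice the nominal sensor noise (6 mm) ischium detection degrades
  noticeably — the prominence threshold equals the noise sd there, and the
  tests document rather than hide that regime.
* Training and evaluation are synthetic-to-synthetic. The original
  cow-trained regression is not public, so the cows-to-heifers transfer
  question is represented only structurally (train on one morphology
  distribution, predict another), not reproduced.
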