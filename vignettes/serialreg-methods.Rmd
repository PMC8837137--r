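---
title: "Expert-supervised rigid registration for serial knee imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expert-supervised rigid registration for serial knee imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialreg)
```

## The problem

Serial imaging of a joint — the same knee scanned twice with the same CT
protocol, or imaged by MRI and CT on the same day — produces image sets in
different coordinate frames. Quantitative analyses that combine parameters
from several acquisitions need those frames registered. Intensity-based
(mutual-information) registration is not always trustworthy when protocols
are optimized for particular tissues, so an *expert-supervised* alternative
is attractive: build a three-dimensional bone surface model by segmenting
one image set, have an operator click a sparse set of **attraction points**
on the bone edges visible in the other image set, and let an algorithm
position the model onto those points.

`serialreg` implements that pipeline and the machinery needed to evaluate
it: contour-based model building, rigid coherent point drift (CPD)
positioning, fiducial-marker and whole-model reference registrations,
surface-distance and volumetric-overlap metrics, and a synthetic
ground-truth generator that stands in for imaging data that cannot be
shared.

All geometry lives in physical millimetres in a right-handed frame.
Registration never happens in voxel indices, so acquisitions with different
voxel sizes (e.g. 0.5 × 0.5 × 0.312 mm CT vs 0.5 mm isotropic MRI) pose no
resolution coupling. Frame labels are opaque: the package never converts
between anatomical orientation conventions (LPS/RAS), because the source
data carries no such metadata through the supported mesh formats.

## Segmentation representation and model building

Segmentations are represented as per-slice closed B-spline contours
(`bspline_contour`, `contour_stack`): ordered control polygons in the slice
plane with a slice coordinate along the out-of-plane axis. Curves use
uniform knots — periodic for closed contours — and are cubic by default;
the upstream segmentation literature does not pin down knot conventions, so
the simplest reproducible choice is used.

`loft_contour_stack()` turns a stack into a closed triangulated mesh:

* each contour is resampled to the same number of approximately
  arc-length-uniform points, with consistent (counter-clockwise) winding;
* adjacent rings are aligned by the cyclic index offset minimizing the
  summed squared inter-ring distance (this is what prevents twist
  artifacts);
* rings are stitched with alternating triangles and the end rings are
  capped by a fan to their centroid (bone cross-sections are near-convex,
  so the fan cannot fold);
* the result must pass the closed/manifold/outward-wound validation;
  a non-positive signed volume aborts with the offending slice pair named.

Branching anatomy (two contours on one slice) is rejected: lofting a
branched stack requires topology decisions this package does not make.

## Rigid coherent point drift

`cpd_rigid(moving, fixed, ...)` fits the rigid motion aligning a moving
point set onto a fixed one. The moving points are centroids of an isotropic
Gaussian mixture with shared variance $\sigma^2$ and a uniform outlier
component of weight $w$; EM alternates posterior computation (E-step) with
a closed-form update of rotation (SVD of the posterior-weighted
cross-covariance with determinant-sign correction, so the solution is never
a reflection), translation (weighted centroids), optional scale, and
$\sigma^2$.

Direction matters and the package fixes it: **mesh samples are the moving
centroids, attraction points the fixed data**. Attraction points are a
sparse subset of the surface; in this direction every data point finds
nearby centroids and uncovered surface regions simply receive low
responsibility, which is what makes partial-tissue registration work.

Defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `w` | 0.1 | outlier mass; expert points are near-clean, but edge ambiguity across modalities justifies a floor |
| `tolerance` | 1e-8 | relative $\sigma^2$ change declaring convergence |
| `max_iterations` | 150 | EM cap |
| `moving_sample_count` | 2000 | farthest-point samples of the model fed to CPD |
| `sigma2_init` | mean pairwise dispersion | standard CPD start |
| `init_translation` | `TRUE` | centroid pre-alignment |

Farthest-point sampling is seeded and deterministic (ties to the lowest
vertex index), so a registration is reproducible from its seed.

Numerical points worth knowing:

* Gaussian kernels below $e^{-45}$ cannot affect the posterior sums at
  double precision; the E-step skips those pairs, and once the interaction
  radius is small relative to the cloud it switches to a uniform-grid
  neighbor search. The result is identical to the dense computation to
  better than $10^{-12}$.
* A vanishing $\sigma^2$ (essentially exact fit) stops the iteration.
* The EM ascends the likelihood, not $\sigma^2$ itself: close to the fixed
  point $\sigma^2$ can tick upward by a few parts in $10^6$ while the pose
  still improves. Tests treat the trace as non-increasing up to $10^{-5}$
  relative slack.
* With very asymmetric set sizes (2000 centroids vs 32 data points) and
  $w > 0$, the posterior can occasionally collapse onto a near-collinear
  support; the fit then returns `converged = FALSE` with the last valid
  pose rather than raising an error. Degenerate *inputs* (collinear sets)
  still error.

## Why CPD alone is not enough, and the surface polish

A subtle but important finding drove one design decision. With the model
represented by a finite centroid cloud, the CPD likelihood optimum does not
coincide with the true pose even for noise-free attraction points lying
exactly on the surface: the mixture rewards proximity to the *centroids*,
not to the *surface*, and along surface-sliding modes (rotations about a
near-symmetry axis of the bone) the optimum sits of the order of a degree
away. This is not a convergence artifact — EM started at the true pose
drifts to the same biased optimum — and it shrinks only about linearly with
the centroid spacing, so no practical sampling density removes it.

`register_model_to_points()` and `register_model_to_model()` therefore
append a **point-to-surface polish**: the attraction points are iteratively
matched to their exact closest points on the triangulated surface (face
interior, edge and vertex cases handled exactly, grid-accelerated) and the
corresponding-point rigid fit is re-solved in closed form, until the pose
change per iteration falls below $10^{-9}$ (radians plus relative
translation). This is classic rigid ICP used as a local refiner; CPD
provides the global alignment that puts it in the right basin. With
noise-free points the combination recovers ground-truth motions to about
$10^{-4}$ degrees; convergence along sliding modes is linear, hence the
generous 2000-iteration cap (typical noisy registrations stop after a few
hundred cheap iterations).

For **partial coverage** (points on, say, the distal 40% of the surface),
the centroid pre-alignment is biased by the uncovered surface and the
default full-dispersion $\sigma^2$ start over-anneals, which can slide the
model along its long axis. The robust recipe — used in the tests — is
`init_translation = FALSE` with `sigma2_init` at the square of the coarse
pre-positioning scale (e.g. 25 mm² when the model is within ~5 mm), which
holds at motions of 15° / 20 mm.

## Reference registrations

* **Fiducial gold standard** — `fit_rigid_corresponding()` is the
  closed-form Kabsch/Umeyama least-squares fit on matched marker pairs,
  with determinant correction; `fiducial_registration_error()` reports the
  RMS residual. With noise-free markers this recovers the true motion to
  machine precision, which is what makes it the reference everything else
  is scored against.
* **Substitution gold standard** — `register_model_to_model()` registers
  the complete model to the complete reference surface (farthest-point
  samples on both sides), the "excessive number of attraction points"
  limit of the expert method. It is used where fiducials are impossible,
  e.g. across modalities.

## Metrics

`mean_absolute_distance()` is the **symmetric** MAD: area-weighted seeded
surface samples of each mesh, exact point-to-triangle distances to the
other mesh, averaged both ways. The same seed drives both samplings, so
`MAD(a, b)` equals `MAD(b, a)` bit for bit. Default 10 000 samples per
surface. The directionality and sampling rule are reporting conventions the
literature leaves open; the symmetric form makes argument-order
independence a testable invariant.

`dice_index()` voxelizes both closed meshes on one shared isotropic grid
covering their padded union bounding box and returns
$2|A \cap B| / (|A| + |B|)$. A voxel is inside iff its **center** is inside
the surface, decided by a vertical-ray parity test; centers that graze an
edge or vertex are re-tested with a deterministic epsilon jitter, so
axis-aligned meshes on aligned grids are handled reproducibly. The default
0.5 mm isotropic grid with 2-voxel padding is commensurate with clinical
knee CT voxel sizes; voxel (0,0,0)'s center sits at the grid origin, the
dominant medical-image convention, and the NIfTI export encodes exactly
that affine so masks and Dice cannot drift by half a voxel.

## The synthetic ground-truth generator

The generator replaces unavailable imaging data, with known truth:

* `make_bone_like_mesh()` — parametric femur-like (tapered shaft flaring
  into condylar lobes) and tibia-like (plateau into shaft) shapes built as
  radial cross-section contour stacks and lofted; a seeded smooth Fourier
  modulation (~2% of radius) varies cases. These are parametric blends,
  not anatomical atlases; they reproduce the size, elongation and moderate
  azimuthal asymmetry of distal femur / proximal tibia segments, not
  anatomical detail.
* `perturb_segmentation()` — interoperator segmentation disagreement as a
  smooth correlated field (radial-basis mixture, default RMS 0.3 mm,
  correlation length 10 mm) displacing vertices along normals. Because two
  operators trace the *same* bone in the *same* image, their disagreement
  carries no net rigid motion: the scalar normal field is orthogonalized
  (area-weighted) against the six rigid-velocity normal components before
  use. Without that projection a whole-surface rigid registration can
  absorb the low-frequency part of the field and score *better* than the
  fiducial truth, which no interoperator study shows.
* `simulate_operator_points()` — area-weighted uniform placement
  (operators are asked only to distribute points roughly homogeneously),
  plus a per-set systematic normal offset (edge-appearance differences
  between modalities) and per-point isotropic localization noise.
  Defaults: 0.3 mm noise intra-protocol; 0.6 mm noise + 0.2 mm normal bias
  for the intermodality regime — bracketing clinical voxel sizes, since
  operator error itself is not quantified anywhere usable.
* `make_ground_truth_case()` — model, a repositioning motion drawn
  uniformly within ±15° / ±20 mm (a judgment call for between-acquisition
  repositioning; nothing publishes this distribution), the perturbed
  target-frame reference, a 4000-point candidate pool, and 5 fiducial
  markers strictly inside the bone, mapped exactly by the true motion.

What passing tests on these data do **not** show: robustness to real CT/MRI
edge appearance, to anatomical shape variation beyond the parametric
family, to branching or pathological anatomy (osteophytes), or to real
operator behavior. They do show that the algorithmic chain — sampling,
CPD, polish, metrics, statistics — is correct and self-consistent under
controlled conditions.

## Study harnesses

`run_point_count_study()` reproduces the attraction-point-count design: per
case, point count (32…1024, doublings) and repeat, subsample the candidate
pool, register, and score against the reference segmentation (MAD, Dice)
and the known motion. Ten cases × 6 counts × 10 repeats per bone kind
gives 600 records per kind. Per-record metrics use 2000 MAD samples per
surface and 1.0 mm Dice voxels — the study's stated problem size, chosen so
a 1200-registration study completes in minutes while per-record metric
noise (≲0.01 mm MAD) stays far below the effects of interest.

`run_method_comparison()` runs the expert method (128 points, the ideal
count), the fiducial gold standard, and the substitution gold standard on
the same cases, with two-sided Wilcoxon signed-rank tests between methods;
the point-count study compares consecutive counts with two-sided rank-sum
tests, Bonferroni-corrected within each bone-and-metric family (family
size 5 at the default counts — the family definition is a package choice,
recorded in the output). Exact p-values are used for small tie-free
samples, the tie-corrected normal approximation otherwise. Quartiles use
the linear-interpolation convention, recorded in every `study_result` so
tables are self-describing.

Whether repeated registrations of the same knee may be pooled as
independent observations in the rank-sum tests is a genuinely open
reporting question; the study result therefore carries both tables —
`tests` pools all cases × repeats (matching summaries computed over 100
registrations per count), and `tests_per_case_median` reduces each case to
one median first. Conclusions below about significance use the pooled
table.

Determinism: everything derives from one `master_seed` — case geometry,
motions, noise, subsampling, farthest-point starts, metric sampling — so
re-running a study reproduces its tables bit-identically.

```{r example, eval = FALSE}
cfg <- study_config(master_seed = 1)
cases <- generate_study_cases(cfg)
study <- run_point_count_study(cases, cfg)
print(study)
```

## Known limitations

* Rigid (optionally scaled) motion only; no affine or nonrigid extension.
* Lofting rejects branching stacks; condyle-resolving slice planes need a
  different meshing strategy.
* The voxelizer assumes well-shaped closed meshes; pathological slivers
  parallel to the casting axis fall back to jittered retests and, in the
  worst case, an empty column.
* The synthetic bones are smooth genus-0 shapes; conclusions about
  cartilage, osteophytes or fractured anatomy are out of reach.
* Intermodality evaluation is emulated as a higher-noise operator regime,
  not as actual multi-contrast image content.
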