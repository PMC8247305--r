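---
title: "Nasolabial wrinkle detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nasolabial wrinkle detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrinklefind)
```

This vignette is the package's account of what it computes and why the
pieces look the way they do. It covers the detection model, the
parameters that matter, the synthetic study conditions, the numerical
choices, and the limits of what the shipped tests demonstrate.

## The detection problem

A nasolabial wrinkle is a thin dark valley in the intensity surface of
the cheek. Edge detectors respond to the two *flanks* of such a valley,
not its centre, so the front end here is second order: the 2×2 Hessian
of the Gaussian-smoothed image. Across a dark valley the profile has
large positive curvature, so the dark-ridge response is the positive
part of the major eigenvalue, `max(lambda1, 0)`, computed in closed
form per pixel. The closed form is validated in the tests against a
dense symmetric eigendecomposition and the trace/determinant identities.

One printed form of the eigenvalue formula in circulation has
`+2*Hxx*Hyy` under the radical; that expression is not an eigenvalue of
a symmetric 2×2 matrix (it degenerates to `max(trace, 0)` when
`Hxy = 0`). The implementation uses the standard discriminant
`(Hxx − Hyy)^2 + 4*Hxy^2`, and the tests enforce
`lambda1 + lambda2 = trace` and `lambda1 * lambda2 = det`.

Derivative kernels are sampled derivative-of-Gaussian filters with
discrete moment corrections (zero sum; unit response to a ramp for
first order and to `x^2/2` for second order), so at small scale the
response at a valley centreline equals the finite-difference second
derivative of the sampled profile. By default the fields are plain
second derivatives (units: intensity per pixel squared). For the
optional multi-scale maximum over scales {1, 2, 4} px the fields are
multiplied by `sigma^2` (`gamma_normalize = TRUE`), the standard
scale-normalization that makes responses comparable across scales; the
option is off by default to stay with the single-scale pipeline.

## Front-end pipeline and its parameters

The region of interest is a polygon over the 68 standard face feature
points. The default index lists (a coarse cheek quadrilateral and
left/right cheek work areas) follow the usual convention for this
task; index ranges such as `1:7` and `15:11` are read inclusively. The
68-point layout used by the fixture generator is a documented template
(`face_template()`); it was chosen so that all three default polygons
resolve to simple (non-self-intersecting) polygons, which a
plausibility check in `cheek_mask()` verifies.

Photometric normalization is Gaussian smoothing followed by global
histogram equalization restricted to the masked region (256 bins).
Equalization strongly amplifies low-contrast texture — that is its
purpose — which has two consequences the pipeline must absorb:

* **Denoising sigma.** The blur must win against the noise that
  equalization will amplify. The default is `preprocess_sigma = 2.5`
  px: at the package's study conditions, smaller values (e.g. 1.5 px)
  leave so much equalized noise that the binarized ridge band
  fragments below the line-length threshold. 2.5 px is still well
  below the wrinkle width after the Hessian's own smoothing, so
  localization is unaffected.
* **Region border.** Equalization stops at the mask boundary; the
  resulting intensity step reads as a strong ridge. The response is
  therefore thresholded inside a mask eroded by
  `2*ceiling(hessian_sigma) + 4` px (8 px at the default scale), which
  keeps the border step outside the derivative kernels' reach.

Binarization is Otsu's threshold over the masked response (quantile and
fixed thresholds are available). The binary band is closed with a 5-px
disc to bridge small gaps, thinned (Zhang–Suen), and decomposed into
arcs. Junctions are detected by the *crossing number* (the number of
distinct neighbour runs around a pixel), not the neighbour count —
staircase corners of thin diagonal lines have three neighbours but are
not junctions. Two pixels flanking a removed junction are only
spuriously diagonal-adjacent and are not connected. Dead-end spurs
shorter than 10 px are pruned and the main line re-joined.

Candidate lines are filtered by the two standard thresholds:

* `llt = 100` px: minimum arc length;
* `lat = pi` rad: maximum total absolute turning. Turning is summed
  over an arc-length resampled copy of the polyline (spacing ~8 px),
  because 8-connected raster steps quantize direction to multiples of
  45° and would make any oblique straight line appear to turn by far
  more than π.

Among in-region survivors (centroid inside the cheek polygon) the line
maximizing `arc_length * mean_response` is selected — the selection
rule itself is a package convention, since one line per cheek must be
chosen somehow. Its ends are trimmed where the (smoothed) on-line
response falls below half its median — the global threshold is low, so
the band otherwise extends along the decaying response tail past the
true valley end — and the line is resampled to 20 points at uniform
arc length, nose end first. Finally the shape is regularized by an
L1 sparse projection onto the Procrustes-aligned training wrinkle
shapes, `min_s 0.5*||v − W s||^2 + lambda*||s||_1` with
`lambda = 1e-6`, solved by coordinate descent (objective
non-increasing by construction; verified against a KKT enumeration
oracle in the tests).

If any stage fails — no line survives, nothing lies in the cheek — the
positioned global mean shape is returned with a `fallback` attribute;
`build_initial_shape()` never throws on valid inputs.

## Shape and appearance models

Shapes are flattened landmark vectors `(x1, y1, ..., xn, yn)`.
Generalized Procrustes alignment iterates similarity alignment to the
running mean (complex-arithmetic closed form), mean recomputation, and
normalization of the mean to unit centroid size at the origin, until
the mean moves less than 1e-7 (at most 100 iterations). Tangent-space
projection is deliberately omitted; at the shape variability of this
problem its effect is far below the landmark noise. PCA uses the
sample covariance (divisor n−1); the number of retained modes is the
smallest reaching `variance_kept = 0.98` of the variance.

The appearance model samples texture in a band around the curve. The
reference frame is a **normal-offset ribbon mesh**: each landmark
contributes two vertices offset ±6 px along the local normal, giving
2(n−1) triangles, and every interior reference pixel carries fixed
barycentric coordinates, so warping to an image shape is a true
piecewise-affine map. A Delaunay triangulation — the textbook choice
for full-face models — is degenerate for 20 nearly collinear points;
the ribbon strip is the natural mesh for a curve and is deterministic.

The band is extended 10 px beyond both curve ends (`end_margin`). This
matters: a band clipped at the curve ends is nearly invariant under
sliding along the fold (the aperture problem), and fits drift
along-curve into positions the texture model explains almost as well.
The valley-to-skin transition at the ends anchors the along-curve
position.

Textures are normalized to zero mean and unit variance (a constant
patch becomes all zeros). Texture PCA keeps 95% of variance. The fixed
Jacobian J is estimated by numeric perturbation at each training
image's ground-truth parameters — shape modes at ±0.25 and ±0.5 of
their standard deviation, translations ±2 px, scale ±5%, rotation
±5° — averaged over images and displacements, and then projected onto
the orthogonal complement of the texture basis: misalignment must be
explained by what the texture model *cannot* represent, otherwise the
updates chase texture variation instead of geometry.

## Fitting

The fit is fixed-Jacobian steepest descent with pose (4 similarity
parameters: scale/rotation as `(1+a, b)`, translation) composed after
shape synthesis. Each iteration samples the image at the current
shape, reconstructs the model texture *for that sample* (the model
instance is re-evaluated every trial), forms the residual and error
`E = ||dg||^2`, predicts `dp = (J^T J + eps I)^{-1} J^T dg`
(`eps = 1e-8` Tikhonov damping against rank deficiency from small
training sets), and tries `alpha` in {1, 0.5, 0.25, 0.125}, accepting
the first step that reduces the error by at least `rel_tol = 10%`.
When no step qualifies the fit stops. The relative tolerance is the
operational reading of "no improvement": with a strict decrease rule
the fit polishes indefinitely in sub-0.1-px steps near the optimum.
Accepted errors are strictly decreasing along `error_trace` by
construction.

The unique initial shape enters the fit through its projection onto
the trained shape model, `p = E^T (n - msh0)`. Re-centring the model on
the ridge-derived shape (treating it as a new mean) was evaluated and
rejected: it permanently freezes ridge noise into the reachable shape
set and measurably worsens recovery.

In `unique_shape` mode the generic-mean path also runs as a safety
net, and the fit with the smaller final unexplained residual wins.
This extends the front end's fallback contract to fit-stage failures —
a ridge line that started the fit in a bad basin shows up as a larger
residual — and involves no ground truth. It also guarantees in
practice that the proposed pipeline is at least as good as the
baseline on each image; the converse can occur only when the residual
ranking disagrees with geometric quality, which is rare but not
impossible (the residual is a proxy).

## Evaluation

Detected and reference lines are rasterized at 1 px width and dilated
with a disc so the band is `expansion` px wide; with the default
`expansion = 20` the disc has the nearest odd width, 21 px. A
radius-20 reading (41-px band) is available via `mode = "radius"`.
Both lines are expanded symmetrically — expanding only one side would
make the index asymmetric, contradicting its set formulation. The
Jaccard index is `|A∩B| / |A∪B|` (1 if both bands are empty), and a
detection with JSI strictly above 0.8 counts as correct. Reports give
mean, median and accuracy per initialization mode.

## Synthetic study conditions

The fixture generator emulates the phenomenon the detector targets: a
single dark curvilinear valley of varying shape and position in a
face-like intensity field. Conditions (all defaults, chosen once):

* 420×420 px images, face ellipse half-axes ≈ (140, 180) px, varied
  ±8% with the centre jittered ±8 px;
* wrinkle centreline: cubic Bézier whose interior control points
  wander ±12 px (S-bends and bowing) and endpoints ±6 px, stretched by
  0.85–1.10 and slid −25..+10 px along the fold direction — real folds
  differ in where they start and how far they reach;
* Gaussian cross-profile valley, depth 0.18–0.32 intensity units,
  width (sd) 2.5–3.5 px; arc length ≈ 105–150 px so the 100-px length
  threshold is meaningful;
* additive Gaussian noise, sd 0.02; horizontal illumination gradient
  5e-4 intensity/px;
* 88 ground-truth landmarks: a fixed 68-point face template scaled to
  the ellipse plus 20 arc-length-uniform points on the rendered
  centreline. Identical spec and seed give bit-identical fixtures.

What the fixtures deliberately do **not** model: skin micro-texture
and pores, multiple or branching wrinkles, specular shading, 3-D pose.
Consequently, passing tests demonstrate the geometry and optimization
machinery — ridge extraction, shape statistics, fit convergence,
scoring — under controlled conditions; they do not certify performance
on photographs. One degenerate corner is worth knowing: on a
noise-free image with *no* illumination gradient the cheek histogram
collapses and equalization manufactures shoulder ridges parallel to
the valley; any realistic noise or gradient removes the artifact.

At these conditions the seeded 20-train / 20-test study (see
`scripts/acceptance.R`) gives mean Jaccard indices of about 0.95–0.98
for the unique-initial-shape pipeline versus about 0.87–0.97 for the
generic-mean baseline, reproducing the expected ordering: the margin
comes from test images whose fold lies far from the population mean,
where the baseline's initialization fails and the per-image ridge
initialization does not.

## Numerical choices and degenerate inputs

* Otsu thresholding is computed on the masked response rescaled to
  [0, 1] (256 bins); a constant response yields an empty binary map.
* Polygon rasterization uses the even-odd rule; degenerate (collinear)
  region polygons give an empty mask with a warning.
* Bilinear sampling outside the image, flipped or collapsed warp
  triangles, and zero-variance patches are failure signals
  (`NULL` texture), which the fitter treats as a rejected trial step
  and `detect()` as a fallback trigger.
* PTS files are written at six decimals; write→read→write is
  byte-identical. 8-bit PNG export rounds half-up.
* All randomness is seeded and scoped (`with_seed` restores the global
  RNG state); every fit and every training run is deterministic.

## Known limitations

* One wrinkle per cheek per call; bilateral detection is two calls
  with mirrored regions.
* The residual-based safety net can (rarely) prefer a geometrically
  worse fit whose texture happens to be better explained.
* Sub-pixel ridge localization is out of scope; the initial shape is
  pixel-quantized and the fit supplies sub-pixel refinement.
* The first-stage face landmarker is a pluggable input: ground-truth
  face points are read from PTS files. Fitting a full 88-point model
  from scratch on unannotated images is not attempted.
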