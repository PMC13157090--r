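---
title: "Metric-scale recovery from a ring fiducial: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-scale recovery from a ring fiducial: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringcal)
```

## The calibration model

A monocular reconstruction determines a scene only up to a similarity
transform: if $P$ is the reconstructed cloud and $Q$ the physical scene
(in millimeters), then $P = s^* R^* Q + t^*$ for some unknown rotation
$R^*$, scale $s^* > 0$ and translation $t^*$. `ringcal` inverts this
transform from a single physical prior: a planar red ring of known
centerline diameter $D_\mathrm{true}$ laid in the scene.

The inversion decomposes into three estimates, each with its own
well-understood estimator:

* **the ring plane**, from PCA of the detected ring cluster. For any
  (noisily) planar set the smallest-eigenvalue eigenvector of the
  covariance is the total-least-squares plane normal; the estimate is
  equivariant under rotations of the input, which is what makes the whole
  pipeline invariant to the unknown $R^*$.
* **the ring circle**, from a two-stage 2D fit in the plane: RANSAC over
  three-point circumcircle hypotheses (robust to residual non-ring
  points), then Gauss–Newton on the geometric objective
  $\sum_i (\lVert p_i - c \rVert - r)^2$. The geometric (as opposed to
  algebraic) objective is the reason occlusion is benign: on a noiseless
  partial arc its minimizer is exactly the generating circle, for *any*
  arc length, while algebraic (Kåsa) fits shrink the radius on short arcs.
  The Kåsa fit is used only where a cheap closed-form circle is wanted
  (the annularity score, a fallback initializer).
* **the scale**, $s = D_\mathrm{true} / D_\mathrm{fitted}$ with
  $D_\mathrm{fitted} = 2r$.

The upright rotation comes from Rodrigues' formula applied to
$z_\mathrm{old}$ (the ring normal) and $z_\mathrm{target} = (0,0,1)$:
$R = I + \sin\theta\,[k]_\times + (1-\cos\theta)\,[k]_\times^2$ with
$k = z_\mathrm{old} \times z_\mathrm{target} / \lVert \cdot \rVert$ and
$\theta = \arccos(z_\mathrm{old} \cdot z_\mathrm{target})$.

Two conventions had to be fixed where notation alone is ambiguous; both
are fixed by testable postconditions rather than guesses:

* **Which way does $R$ map?** The stored rotation follows the plant
  transform convention $P' = R^{\mathsf T} P$, $P'' = s P'$: the
  *transpose* of the stored matrix maps reconstruction to world. The
  binding contract, asserted in the tests, is that the ring normal maps to
  world $+z$.
* **Normal sign.** PCA eigenvectors have arbitrary sign. The normal is
  oriented so the plant centroid has a positive component along it —
  plants grow above the ring plane. A plant centroid within $10^{-9}$
  ring-radii of the plane is reported as an ambiguous-orientation error.
  Scenes mirrored through the ring plane therefore calibrate to the same
  world geometry.

A third convention is ours outright: the paper-level model supplies only
$R$ and $s$, so the package fixes the world origin at the fitted ring
center with the ring plane at $z = 0$. Heights and vertical distributions
are then measured from the ground plane, which is what the trait suite
wants. `translate = FALSE` in the config disables it.

## Ring detection

Detection is done in 3D on the per-point colors (not on source images):
this decouples the tool from the reconstruction toolchain entirely — it
consumes any colored PLY.

* **Color model.** HSV thresholding with a wrapped red hue interval,
  defaults $[0,20) \cup [340,360)$ degrees, saturation $\ge 0.4$, value
  $\ge 0.2$. Print pigments and illumination move these; all six numbers
  are config keys. There is no learned component.
* **Clustering.** Single-linkage (connected components at radius
  $\varepsilon$). The default $\varepsilon$ is $4\times$ the median
  nearest-neighbor distance of the red subset. The multiplier is
  deliberately above the percolation radius of uniform surface sampling:
  for a Poisson surface process, connectivity requires roughly
  $\lambda \pi \varepsilon^2 \gtrsim 4.5$, and a $2\times$ multiple sits
  *below* that bound at any density — it fragments a finite-width ring
  stroke into dozens of arcs. $4\times$ is still scale-free (the cloud's
  units are unknown at this stage).
* **Cluster scores.** *Planarity* = smallest/largest covariance
  eigenvalue ratio ($\le 0.05$ by default): near 0 for planes at any
  tilt, $\approx 1$ for spheres and solids. *Annularity* = sd/mean of
  in-plane radial distances about the center of a Kåsa circle fit
  ($\le 0.25$): a full or partial ring stroke scores its relative stroke
  width ($\approx 0.03$ at defaults), filled disks and projected spheres
  score $\gtrsim 0.28$. Measuring from a fitted circle center rather than
  the cluster centroid is essential: the centroid of a quarter-arc lies
  far off the circle and would score the arc as non-annular, defeating
  occlusion robustness. Ties between equal-size passing clusters break by
  lower annularity, then lower planarity — deterministic.
* **Cleaning.** Statistical outlier removal (mean distance to $k = 8$
  neighbors, threshold mean $+ 2$ sd) runs on the ring cluster before the
  plane fit, where it stabilizes the PCA against multi-view-stereo
  floaters. The *circle* fit, however, is run on every raw cluster point
  whose out-of-plane residual passes a robust gate
  ($3 \times$ MAD of the cleaned residuals): discarding valid stroke
  points from the precision stage would only waste statistical
  efficiency, and the gate alone removes gross off-plane junk.

## Circle-fit tolerances

RANSAC defaults: 2000 iterations, minimum inlier fraction 0.3 (a ring
can be 70% hidden before the fit refuses), fixed seed 0 — calibration is
bit-reproducible. The inlier tolerance defaults to

$$\max(0.02\, \hat r,\; 2.5 \times 1.4826\,\mathrm{MAD}(d_i))$$

where $\hat r$ is the median in-plane distance to the centroid. The
second term matters: a printed ring stroke has finite width (10 mm on a
200 mm ring at defaults), and a tolerance of $0.02\hat r = 2$ mm would
select an arbitrary 4 mm radial sub-band of the 10 mm stroke — every
such sub-band is a fixed point of refit-and-reselect iteration, pinning
the radius anywhere within $\pm 3$ mm ($\approx 3\%$ scale error). With
the MAD term the whole stroke is inlier and the geometric fit converges
to the stroke centerline, which is the quantity $D_\mathrm{true}$
describes. Gauss–Newton runs with step-halving (the objective never
increases), converges to relative tolerance $10^{-14}$, caps at 100
iterations and flags non-convergence with a warning. The inlier set is
re-derived about each refined circle until stable (at most 5 rounds).

Degenerate cases: parallel Rodrigues inputs return the identity exactly;
antiparallel inputs (undefined cross product) return a 180° rotation
about a deterministic axis orthogonal to $z_\mathrm{old}$; collinear
point sets are a degenerate-geometry error for both the plane frame and
the 3-point circumcircle (such samples are skipped inside RANSAC).

## Trait definitions

Traits with no canonical formula are documented choices, not claims:

* **Plant height**: difference of the 99.9th and 0.1th z-percentiles.
  Percentile trimming rejects isolated floaters above the canopy; the
  narrow trim keeps the estimator bias at 0.2% of the span for a
  uniformly filled vertical profile (a 0.5/99.5 trim would shave a full
  1%). Percentiles 100/0 recover the raw bounding box.
* **Canopy width**: diameter of the convex hull of the xy projection
  (exact, via the hull vertices).
* **Canopy projection area** (convex) and **main projection area**
  (concave): the hull area and the occupancy-grid area at 2 mm cells.
  Both are reported because "projected area" is used in both senses in
  the phenotyping literature; the grid reading excludes holes and
  concavities and is never larger than the hull reading.
* **Total leaf area**: the cloud is cut into cubic patches of
  $15\times$ the median point spacing, each patch plus a $6\times$
  margin is projected on its PCA plane and Delaunay-triangulated,
  triangles with any edge over $8\times$ the spacing are pruned (they
  bridge gaps or holes; Delaunay edges of uniform sampling run 2–4
  spacings), and each triangle is counted once, assigned to the patch
  holding its centroid. Every threshold is a multiple of the measured
  spacing, so the estimator is exactly scale-equivariant. Its contract,
  enforced in the tests: a densely sampled planar disk recovers
  $\pi r^2$ within 5%. Note the estimator measures *all* surfaces in the
  cloud — stems included — so analytic comparisons use stemless fixtures
  or add the analytic stem area.
* **Compactness**: occupied-voxel volume over 3D convex-hull volume
  (5 mm voxels), clipped to $[0,1]$. **Spatial occupancy**: occupied
  voxels over bounding-box grid voxels. Both are
  discretization-dependent; the resolutions are echoed into every
  report.

The 3D hull and the 2D Delaunay triangulation are implemented in the
package (incremental hull; Bowyer–Watson) and validated against analytic
shapes in the tests.

## What the synthetic scenes emulate — and what they do not

`make_scene()` builds: a ring whose points sit on a uniform angular grid
with radial stroke offsets drawn in symmetric $\pm$ pairs about the
centerline; a stylized plant (planar disk leaf, tilted elliptical leaves
on a stem, or a solid box) with analytic height and surface areas; red
clutter primitives; hue/saturation/value jitter with a brightness-shift
term for illumination; isotropic Gaussian coordinate noise; contiguous
arc occlusion (the hardest geometry for corner-based markers — a leaf
lying over one side); ring inclination; and a final similarity transform
with log-uniform scale.

The paired radial sampling is a deliberate design: it makes radius and
angle exactly independent in-sample, so the geometric-LS circle of the
noiseless ring is *exactly* the centerline for any contiguous arc. The
generator's ground truth is thereby analytic rather than asymptotic, and
noiseless recovery can be asserted at $10^{-6}$ instead of at a
sample-size-dependent tolerance. The stroke width itself (10 mm) is a
config default; the physical artwork's stroke is not pinned down by the
source material.

What the generator does **not** emulate: the anisotropic, view-dependent
error structure of real multi-view stereo (noise here is isotropic
Gaussian), color bleeding at leaf/ring boundaries, shadows crossing the
ring, non-planar (curled) paper, or multiple rings. Passing the synthetic
suite therefore demonstrates the geometry and the estimators, not
photometric robustness on real captures; the HSV thresholds in particular
should be expected to need tuning per camera and print.

## Problem sizes and determinism

The test and validation suites run scenes of 1000–1500 ring points and
600–1600 plant points, 20 seeds per condition — sizes where every
estimator is deep in its working regime while a full validation pass
stays in the tens of seconds. Neighbor searches are chunked brute force,
adequate to a few tens of thousands of points per cloud.

All stochastic stages (RANSAC, generators, sweeps) take explicit seeds,
restore the caller's RNG state, and two runs with identical inputs and
config produce byte-identical artifacts; the effective configuration and
seeds are embedded in every output file.

## Known limitations

* One ring per scene; multi-marker fusion is out of scope.
* Ring inclination beyond 90° relative to the plant's up-direction would
  flip the recovered orientation (the plant-above-plane rule).
* Surfaces closer together than the meshing patch size merge in the
  surface-area estimate.
* The azimuth about the world z-axis is unconstrained by a rotationally
  symmetric marker; all reported traits are azimuth-invariant (exactly or
  to hull/grid discretization).
* Very sparse clouds (under ~50 distinct points for meshing, under the
  `min_cluster` size for detection) are rejected with diagnostic errors
  rather than estimated.
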