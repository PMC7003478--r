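---
title: "Parcellation-constrained fiber bundling: model and methods"
author: "parcbundle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellation-constrained fiber bundling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Whole-brain tractography reconstructs tens of thousands of streamlines
("fibers") per subject. For anatomically interpretable analysis these must be
grouped into bundles that connect pairs of labeled gray-matter regions
(ROIs). Pure clustering yields coherent but anatomically unmoored bundles;
pure atlas lookup (assigning each fiber to the ROI pair nearest its
endpoints) respects the atlas but inherits every registration and tracking
error at the fiber terminals. `parcbundle` implements a probabilistic model
that optimizes both properties at once, for one subject and for a group of
subjects bundled jointly with nonrigid alignment.

# The model

A fiber $x$ is an ordered 3-D polyline with a fixed point count $m$; all
geometry lives in continuous, 0-based voxel coordinates of the label grid
(point $(0,0,0)$ is the center of the corner voxel), so all $\sigma$ values
and metrics below are in voxels. The bundle connecting ROIs $(l_1, l_2)$ is
summarized by a centroid curve $\mu_{l_1,l_2}$ with $m$ points.

Two Gaussian factors define the likelihood of a fiber under a bundle:

* **Shape term.** Fiber points are independent isotropic Gaussians around
  the corresponding centroid points,
  $\log p(x \mid \mu) = \sum_{i=1}^m \left[-\tfrac32\log(2\pi\sigma_b^2)
  - \lVert x_i - \mu_i\rVert^2 / 2\sigma_b^2\right]$.
  A single $\sigma_b$ (`sigmaBundle`) is shared by all points of all
  bundles; many bundles are small, and point-specific covariances would be
  unstable to estimate and invert.

* **Terminal projection term.** Each terminal $r$ is projected to its
  closest point in ROI $l$; the likelihood is an isotropic Gaussian in the
  projection distance $\phi_l(r)$, evaluated from a precomputed Euclidean
  distance transform of the ROI mask. The correspondence between the two
  terminals and the two ROIs is the one with the greater joint probability.

The product of the two factors scores a fiber against a bundle. The two
factors have different dimensionality (a $3m$-dimensional density times a
6-dimensional one); following the model's definition the product is used
directly as an unnormalized score, which is harmless because memberships
are normalized per fiber across bundles.

The whole brain is a mixture over all ROI pairs with all mixture proportions
fixed to one — corpus-callosum-sized bundles would otherwise absorb fibers
from small bundles — leaving the centroids as the only estimated parameters.

# Single-subject EM

`runEM()` alternates:

* **E-step**: memberships $m_{j,(l_1,l_2)}$ are the per-fiber softmax of the
  joint log-likelihoods over bundles.
* **M-step**: each centroid becomes the membership-weighted point-wise mean
  of the orientation-normalized fibers.

Initialization assigns every fiber to the ROI pair closest to its two
terminals and averages each pair's members. Iteration stops when the number
of hard-assignment changes is at most `changeThreshold` (default 20 fibers)
or after `maxIterations` (default 10).

**Sparsification.** A fiber's membership in a bundle is fixed at zero — and
never evaluated — when no terminal pairing places both terminals within
`gateMultiplier * sigmaRoi` (default $3\sigma_{ROI}$) of the bundle's ROIs.
Fibers gated from every bundle are reported as unassigned and excluded from
centroid updates and metrics.

**Baseline modes.** `mode = "clustering_only"` drops the terminal factor and
the gate (pure curve clustering); `mode = "roi_only"` returns the
closest-ROI-pair labeling unrefined. These are the two ends of the
$\sigma_{ROI}$ spectrum: as $\sigma_{ROI} \to 0$ the constrained algorithm
reduces to closest-pair labeling, and as $\sigma_{ROI} \to \infty$ to pure
clustering — both limits are verified in the test suite.

# Groupwise EM

For $S$ subjects the model couples common centroids $\mu_k$ with one
transform $T^s$ per subject mapping its native space into the common (label
grid) space; the parcellation and its distance fields are never warped. Each
iteration:

1. E-step per subject against the common centroids, with fibers and
   terminals warped by the current $T^s$;
2. centroid update: pooled membership-weighted mean of all subjects' warped
   fibers, normalized per bundle;
3. per-subject summary: native-space membership-weighted bundle centroids
   with their responsibility masses;
4. transform update: a weighted thin-plate-spline (TPS) fit from each
   subject's bundle-centroid points (every 3rd point of each curve) to the
   corresponding common-centroid points, weighted by bundle mass. Aligning
   centroids instead of all fibers makes this step's cost proportional to
   the number of bundles.

Two printed forms of the update equations are internally inconsistent in
their normalizations; this implementation uses the per-bundle normalization
for the common centroids (the printed pooled-over-bundles denominator would
not reduce to a mean for a single bundle; it is still switchable via
`updateCommonCentroids(denominator = "pooled_over_k")` for comparison) and
the per-subject, per-bundle normalized weighted mean for the subject
summaries.

**Initialization.** Each subject is rigidly pre-aligned (orthogonal
Procrustes) before the first iteration. The fit is anchored to the label
grid: source points are the endpoints of the subject's closest-ROI-pair
bundle centroids, targets the centers of mass of the corresponding ROIs,
weighted by bundle size. This is deterministic, anchored to the common
space (so a purely rigidly displaced subject is restored to it, not to a
drifting group mean), and rough by design — the TPS refinement does the
rest.

**Finalization.** Within an iteration the centroid update holds transforms
at their previous value (the model's block order). When the
assignment-change rule stops the loop, one extra centroid update under the
final transforms is applied so that the returned (centroids, transforms)
pair is mutually consistent; otherwise the reported model is systematically
stale by one transform update.

**Baselines.** `method = "independent"` bundles each subject separately with
no alignment; `"posthoc_tps"` additionally fits one TPS per subject mapping
its centroids onto the group means afterwards; `"pooled"` concatenates all
subjects into one fiber set and runs single-subject EM in the common space.

# Metrics and pruning

* `meanInbundleVariation()` (MIV): mean fiber-to-assigned-centroid distance;
  coherence.
* `meanEndToRoiDistance()` (MED): mean summed terminal-to-assigned-ROI
  distance; anatomical consistency.
* `meanBundleCentroidDifference()` (MBCD): mean distance between per-subject
  centroids (in common space) and the group centroid; cross-subject
  consistency.
* `groupwiseMIV()` (GMIV): mean distance of all subjects' warped fibers to
  their assigned common centroids.

The curve-to-curve distance underlying all four is the mean
corresponding-point Euclidean distance after resampling to a common $m$ and
orientation normalization — the distance implied by the isotropic shape
model. `pruneInconsistentBundles()` retains a bundle only if it is present
in every subject and its mean per-subject centroid difference is at most 2.5
voxels (equality retains; the threshold is configurable); bundles produced
by tracking artifacts and misregistration fail this cross-subject
consistency filter.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigmaBundle` | 2 | voxels | curve tightness; larger = looser bundles |
| `sigmaRoi` | 2 | voxels | trust in the label mapping at terminals |
| `m` | 20 | points | arc-length resample count per fiber |
| `maxIterations` | 10 | – | EM iteration cap |
| `changeThreshold` | 20 (single), 20·S (group) | fibers | convergence rule |
| `gateMultiplier` | 3 | – | sparsification gate at `gate * sigmaRoi` |
| `mStepWeights` | `"soft"` | – | soft vs hard centroid updates |
| TPS `lambda` | 0.01 × bbox diagonal | – | warp regularization; 0 interpolates |
| prune threshold | 2.5 | voxels | cross-subject consistency cut |

$\sigma$ defaults follow the model's working settings (both 2 voxels);
$m = 20$ is a balance between curve fidelity and EM cost (the model does
not fix it; it is configurable). The hard-assignment rule used for
convergence counting breaks ties toward the smaller canonical bundle key so
reruns are deterministic. The soft/hard M-step switch exists because the
hard assignment could be read either as replacing the memberships in the
centroid update or as serving only the convergence count; the default is
soft, since the update equation is written over memberships.

# Numerical choices

* All likelihoods are computed in log space with log-sum-exp normalization;
  the 20-point product otherwise underflows double precision at moderate
  distances.
* Distance fields are exact squared Euclidean distance transforms
  (separable lower-envelope algorithm, implemented in C++), queried by
  trilinear interpolation with coordinates clamped to the grid; terminals
  are continuous coordinates and nearest-voxel lookup would quantize the
  projection term.
* Fibers are resampled to $m$ points equally spaced in arc length only when
  their stored point count differs from $m$; endpoints are preserved
  exactly.
* Orientation (streamlines carry no canonical direction) is resolved per
  (fiber, centroid) pair by the smaller squared distance at
  likelihood/update time, and by the winning terminal pairing at
  initialization, before centroids exist.
* A (subject, bundle) pair counts as present only when its responsibility
  mass is at least half a fiber (`minMass = 0.5` in `subjectCentroids()`).
  Below that, the weighted "centroid" renormalizes responsibility dust from
  unrelated fibers and can sit voxels away from anything real, corrupting
  MBCD and the transform fit.
* Same-ROI fibers (both terminals closest to one label) have no valid
  bundle; at initialization the worse-matching terminal is moved to its
  second-closest label, and EM may reassign the fiber later. Dropping such
  fibers silently would bias MIV.
* The TPS kernel is the 3-D biharmonic $U(r) = r$; the default
  regularization $\lambda = 0.01 \times$ bounding-box diagonal guards
  against folding when control points are few, and $\lambda = 0$
  (interpolating) is available and used in the recovery tests.

# The synthetic phantom

`makePhantom()` / `makeGroup()` generate the ground-truthed data every test
runs on: ball-shaped ROIs at Poisson-disk-sampled centers (L = 12, radius 4
on a 48³ grid by default), K = 10 quadratic-Bezier centroids between ROI
centers with a modest random bow (max discrete turning angle well under the
tracking-style 41° limit), 50 fibers per bundle sampled as centroid plus
i.i.d. isotropic point noise (1 voxel) with extra terminal jitter (1 voxel,
mimicking error accumulation at streamline endpoints) and random point-order
reversal, and per-subject smooth TPS misregistration warps of a chosen
magnitude (fold-free by rejection). Sub-seeds are derived per component, so
changing the fiber count does not move the ROIs.

The phantom emulates exactly the generative assumptions of the model —
which is the point for correctness testing, and the caveat for
generalization. Real tractography has curved, crossing, partial and
spurious streamlines, non-Gaussian and spatially correlated errors,
irregular ROI shapes, and bundle overlap. Passing recovery tests on the
phantom demonstrates that the estimator is implemented correctly, not that
the model is adequate for any given dataset.

One consequence observed in the acceptance suite: with radius-4 ROIs,
1-voxel jitter and 2-voxel warps, every method assigns essentially all
fibers correctly, so comparisons that depend on bundling *mistakes* —
the coherence/anatomy trade-off as $\sigma_{ROI}$ varies, and the margin of
the full groupwise method over the post-hoc-TPS baseline on the MBCD
metric — become degenerate: the corresponding curves are flat (up to a
small opposite-sign effect of the $3\sigma$ gate excluding outlier fibers
at $\sigma_{ROI} = 0.5$) or razor-thin. The full groupwise method does beat
the no-alignment baselines (independent and pooled) decisively on every
seed, and the post-hoc baseline on mean GMIV.

# Problem sizes in the test suite

Unit tests use 36³-grid phantoms with 6 ROIs, 4–5 bundles and 6–10 fibers
per bundle; property tests loop over 4–20 seeded phantoms; the acceptance
checks use the default 48³ phantom (500 fibers) and 5-subject groups (2500
fibers, 20 seeds for the method comparison). The whole suite runs in a few
minutes on one CPU.

# Known limitations

* The mixture has no background/outlier component: every non-gated fiber is
  forced into some bundle.
* $\sigma_{bundle}$ and $\sigma_{ROI}$ are fixed inputs, not estimated.
* The common space must be the label-grid space; the parcellation is never
  deformed.
* TPS alignment uses downsampled centroids, so very short or single-fiber
  bundles contribute little to (and may destabilize) the transform fit —
  the mass weighting mitigates this.
* TRK support covers the common version-2 layout (voxel-mm points with a
  header voxel-to-world matrix); exotic orientation headers are not
  interpreted.
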