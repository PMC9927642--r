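---
title: "Distance-field stem-leaf segmentation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-field stem-leaf segmentation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfsp)
```

# The problem and the model

Organ-level phenotyping of maize from 3-D scans needs every point of a
single-plant cloud assigned to an organ instance: the stem, and each leaf
individually. Local surface features alone cannot do this (a mid-blade patch
of one leaf looks exactly like a mid-blade patch of another), and skeleton
methods are slow and brittle. The pipeline implemented here exploits a
global structural fact about single-stalk plants: *the terminal regions of
organs — leaf tips and the bottom of the stem — are the parts of the plant
most dispersed in space*. Encoding that fact as a scalar field turns organ
localization into mode seeking.

## The Minkowski distance field

For a cloud $P = \{p_1,\dots,p_n\}$ and a base point $p_B \notin P$, the
field is

$$F(p_i) = \lVert p_i - p_B\rVert_2^{\alpha}, \qquad \alpha \ge 1.$$

With $p_B$ at the cloud centroid, every organ end is a local maximum of $F$
along the plant surface. The exponent $\alpha$ does not change the ordering
of field values (the field's argsort is the same for every
$\alpha \ge 1$); it changes *contrast* — how fast the field decays,
relatively, as one moves inward from an organ tip. Contrast is what the
clusterer's level-ratio test sees, so $\alpha$ effectively rescales the
cluster-core sizes: the distance-ratio threshold that delimits a core is
$(1-\beta)^{1/\alpha}$.

## Mode seeking on the field

Cluster cores are recovered by a persistence sweep over the symmetrized
k-nearest-neighbor graph (the union of directed k-NN relations; the union
rather than mutual k-NN keeps thin leaf tips connected). Points are
processed in decreasing field order while a union-find tracks connected
components. A component with peak value $v$ survives as a *cluster core*
exactly when it is absorbed by a higher-peaked component only below level
$(1-\beta)v$; its membership is the connected component of the upper level
set $\{F > (1-\beta)v\}$ containing its peak, captured as a snapshot at the
moment the sweep crosses that threshold. Remaining points are attached by
hill climbing: each point links to the nearest point in its own k-NN list
with a strictly greater field value, and chains are followed into a core.

Two parameter semantics follow directly and are enforced as tests: the
number of cores is non-increasing in $k$ (more edges merge components
earlier) and non-increasing in $\beta$ (a weaker persistence requirement is
harder to fail).

An important realization detail: membership is the *threshold snapshot*,
not the component membership at absorption time. The two differ whenever a
low-field bridge joins extra points to a component between the threshold
crossing and the absorption; with the absorption-time reading we observed
stem cores swallowing mid-blade bands of the bottom leaf through exactly
such bridges, which inflates the region-growing radius downstream. The
snapshot reading is also the published definition of the core.

## Stem extraction

1. **Organ ends.** Field from the centroid ($\alpha_1 = 5$), core recovery
   only, with $K_1 = 32$, $\beta_1 = 0.85$ at the 15,000-point working
   resolution.
2. **Which core is the stem?** For each core, the mean over members of
   $\lambda_3(\lambda_1-\lambda_2)/\lambda_1$, the eigenvalues taken from
   the covariance of each member's $K_f = 64$ nearest neighbors in the full
   cloud. $(\lambda_1-\lambda_2)/\lambda_1$ is linearity; $\lambda_3$
   penalizes flat (leaf-like) patches. A cylindrical stem-bottom patch is
   both elongated and non-flat, so the stem core is the argmax. Units
   matter here: $\lambda_3$ carries squared scanner units, so the feature
   is rigid-invariant but scales with the square of plant scale — fine,
   since only the argmax is used.
3. **Growth direction and alignment.** The component-wise median of unit
   vectors from the stem core's median point to each leaf core's median
   point; alternate phyllotaxy makes the lateral components cancel. The
   plant is translated so the stem base is the origin, rotated so the
   direction is +z, and rotated about z so the principal components of the
   ground-plane projection align with x/y (x sign fixed by non-negative
   skewness; later stages only consume z).
4. **Region growing (MNVG).** From the origin, repeatedly add all points
   within radius $r$ of the seed, step the seed by $r$ along the
   direction-smoothed median of unit vectors to the captured points
   ($v_j \leftarrow (v_j + v_{j-1})/\lVert\cdot\rVert$, $v_0 = 0$, which
   bounds the turn per iteration), and stop before adding the sphere whose
   center would exceed height $\mu h$, $h$ being the aligned cloud's
   maximum z. $r$ defaults to the diameter of the stem cluster core.

## Leaf instances

After removing the stem set, a second pass runs on the aligned leaf cloud
with the base point at the origin (the stem base — not in the cloud, so the
field is defined by construction), $\alpha_2 = 9$, $K_2 = 32$,
$\beta_2 = 0.85$, this time with hill-climbing assignment, one instance per
core, renumbered by descending size. The sharper exponent matters for
wrapped new leaves: their tips protrude at distinct heights while their
sheaths touch far below, and $\alpha_2 = 9$ makes the touching region's
field a tiny fraction of the tip field, so each tip survives the
persistence test. Plain Euclidean clustering, at any tolerance that keeps
single blades whole, merges the whorl — the contrast the acceptance suite
reproduces.

# Parameters

| Parameter | Meaning | Default (15,000 pts) | 4096-pt preset |
|---|---|---|---|
| `target_n` | working resolution after voxel+FPS down-sampling | 15000 | 4096 |
| `alpha1` | field exponent, stem stage | 5 | 5 |
| `k1`, `beta1` | k-NN size / level ratio, stem stage | 32 / 0.85 | 8 / 0.85 |
| `k_f` | PCA neighborhood for the stem feature | 64 | 16 |
| `mu` | growth stop fraction of plant height | 0.30 | 0.30 |
| `r` | growth radius | stem-core diameter | same |
| `alpha2`, `k2`, `beta2` | leaf stage | 9 / 32 / 0.85 | 9 / 8 / 0.85 |

All coordinates are unit-agnostic; nothing is rescaled on read. $\mu = 0.30$
suits pre-jointing plants whose height is dominated by leaves; taller stems
under-segment at 0.30 and need a larger $\mu$ — a stated, deliberate
limitation of the height-based stop rule.

# The synthetic world

There is no deposited scan set to regress against, so the package carries a
labeled generator (`plant_spec()` / `generate_plant()`) whose defaults
state one fixed world; they were chosen from maize morphology, not adjusted
against test outcomes:

* **Stage allometry.** Stalk length $60 + 15\,n_\text{leaves}$ mm, stalk
  radius $2.5 + 0.9\,n_\text{leaves}$ mm, longest leaf
  $220 + 32\,n_\text{leaves}$ mm with a sine length profile peaking
  mid-rank. A 3-leaf seedling and a 12-leaf plant are different objects,
  and several pipeline properties (neighborhood size vs. stalk curvature,
  junction geometry) only come out right when dimensions scale together.
* **The "stem" is the sheath column.** Manual ground truth for maize scans
  labels the stalk *plus the wrapped leaf sheaths* as stem, up to the
  topmost ligule; blades leave the column at their ligule. The generator
  does the same (one cylinder, label 0), which is also what makes the
  region-growing radius sweep mostly stem-true points.
* **Blade shape.** Blades are ruled surfaces along arching midribs
  (elevation falling linearly along the blade, giving closed-form
  parabola-like arcs), narrow at the ligule and widest mid-span. Mature
  leaves leave at ~45° and arch flat and wide; only the youngest one or two
  expanded leaves stand steeply by the whorl.
* **The whorl.** Wrapped new leaves are concentric arcs nested within
  1–2 mm, contiguous with the column, encircling it at the base (>180°
  total wrap) and unrolling into flat strips whose tips protrude at
  1.9–2.6× the column height. Nesting this tight is what makes Euclidean
  clustering fail on the apex while the distance field still separates the
  tips; it also keeps mixed-layer PCA neighborhoods thin (small
  $\lambda_3$), so whorl tips do not masquerade as stems.
* **Noise and occlusion.** Isotropic Gaussian noise of 0.1 mm (the
  scanner-resolution scale; the instrument's stated accuracy is 0.03 mm)
  and 2% dropout in 8-mm spherical holes placed in the cluttered mid-canopy
  interior, where a handheld scanner is actually blocked. Holes are not
  placed on the open stalk bottom or isolated tips: early versions that
  severed thin distal blades or the stem base produced failure modes
  (spurious split instances, missing stem bottoms) at rates far above what
  handheld scans show.

What a green test does **not** establish: robustness to real sensor
artifacts (registration seams, anisotropic noise, specular dropout on wet
tissue), to pot/soil points, or to architectures outside a single-stalk
plant with alternate leaves. Blades here are zero-thickness surfaces; real
scans show two offset sides of each blade.

# Numerical choices

* Ties everywhere break to the lower point index (field sort, k-NN lists,
  core peaks), making every stage deterministic; the only RNG in the
  pipeline is the base-point collision perturbation, which is fix-seeded.
* "Median" of unit vectors is the component-wise median (even counts: mean
  of the middle pair) followed by renormalization; the geometric median
  was rejected as costlier and redundant next to the direction-smoothing
  step.
* The base-point collision test is exact float equality, matching the
  field's definition; the perturbation magnitude is $10^{-6}\times$ the
  bounding-box diagonal.
* PCA neighborhoods include the query point; covariance uses the $n-1$
  denominator (only eigenvalue ratios and an argmax are consumed).
* Voxel representative = the existing input point nearest the voxel cube
  center, never an averaged point, so labels survive down-sampling and
  coordinates are never invented.
* An empty growth sphere after the first iteration terminates MNVG quietly
  (a gap in the cloud); an empty *first* sphere is an error (seed off the
  plant).
* Degenerate PCA neighborhoods (all points coincident) yield $(0,0,0)$ and
  a zero feature contribution; $\lambda_1 = 0$ contributes 0.

# Known limitations

* Single-stalk architectures only; the region grower cannot follow
  branches.
* The height-based stop ($\mu h$) under-segments tall stems and slightly
  overruns into the whorl base on short ones; junction points within the
  growth radius of the column are claimed by the stem. These junction
  errors dominate the residual error of the end-to-end suite.
* Over-segmentation of a leaf whose tip region is fragmented (occlusion)
  is reproduced deliberately, not patched by post-hoc merging.
* The stem feature is sensitive to severe missing data at the stem bottom;
  if the bottom cap's cylindrical patch is gone, another core can win.
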