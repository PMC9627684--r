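---
title: "Skeleton-based morphometry of the utero-placental vasculature: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-based morphometry of the utero-placental vasculature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upvs)
```

## The measurement problem

Power-Doppler (PD) ultrasound encodes the magnitude of moving-blood signal
per voxel as an 8-bit number. In the first trimester the utero-placental
vasculature — the distal spiral arteries and their anastomoses in the
decidua and placental bed — appears as a branching, tree-to-mesh-like PD
structure. Volumetric summaries (how much vascular signal) miss the
morphology (how the vasculature is organized); the approach implemented here
reduces the thresholded vascular volume to a one-voxel-wide skeleton whose
local connectivity *is* the morphology, and then counts and measures that
skeleton.

The pipeline is strictly deterministic: a fixed input volume, mask and
configuration always produce a byte-identical results row.

## Stage 1: vascular volume (uPVV)

Voxels with intensity at or above a threshold τ inside the vascular region
mask form the vascular selection. The defaults are:

* `threshold = 100` (of 255) — the standardized visualization threshold for
  this application. The comparison is **inclusive** (`≥ 100`) by default;
  the boundary convention is exposed as `inclusive = FALSE` for users who
  want a strict `>` comparison, because usage in the field is ambiguous at
  exactly the threshold value. At clinical signal distributions the
  difference is a handful of voxels.
* `min_component_voxels = 0` — no despeckling. Artefact removal in the
  source workflow is manual (a virtual eraser in a VR environment), so the
  automated pipeline must not silently drop signal; the component filter
  exists for phantom experiments only.

`uPVV = n_selected · sx·sy·sz / 1000` (cm³) exactly, with spacing in mm.
Placental volume (PV) enters either as a placenta mask (its voxel volume) or
as a scalar per subject, since manual rotational tracing is outside this
package's scope.

## Stage 2: skeletonization

The skeleton is computed by homotopic thinning with the standard digital
topology for this task: 26-connected foreground, 6-connected background. A
voxel may be deleted only if it is *simple* — deletion leaves both the local
foreground 26-component count and the local background 6-component count at
one (Bertrand–Malandain characterization) — so the skeleton provably has the
same number of connected components, and no new loops or cavities, as the
selection.

Deletion order matters for centredness. Candidates are processed outermost
first, ordered by the anisotropic Euclidean distance transform (EDT,
computed by the separable lower-envelope algorithm), with ties broken on the
linear voxel index so results are reproducible to the bit. Three refinements
deal with well-known failure modes of naive thinning:

1. **Anchoring.** Local maxima of the EDT (approximate centers of maximal
   inscribed balls) may not be deleted in the first pass. Without this, the
   ends of a tube erode longitudinally — for some orientations a tube can
   collapse to a short stub before any protected endpoint forms.
2. **Ridge-aware endpoint protection.** A voxel with a single neighbour is
   kept only if it is anchored. True tube tips lie on the EDT ridge;
   unanchored tips are parasitic strands created by boundary discretization
   and are allowed to retract.
3. **Width reduction and taut-string cleanup.** After the anchored pass, a
   pass that deletes only voxels with ≥ 3 neighbours reduces residual
   two-voxel-wide ridge plateaus, and a final pass removes degree-2 corner
   voxels whose two neighbours are mutually adjacent (redundant corners and
   3-clique remnants). These two passes iterate to a fixpoint; neither can
   shorten a one-voxel-wide curve.

**Spur pruning.** Even a well-centred thinning sprouts spurious terminal
branches: short bumps at junctions and, occasionally, strands running
parallel to a true centerline inside the same vessel. The pruning criterion
is reconstruction-preserving: a terminal branch (endpoint up to the first
junction) is deleted only if every one of its voxels lies within the
maximal inscribed ball (EDT radius, plus half a voxel of slack) of some
skeleton voxel outside the branch — i.e. only if removing it leaves the
volume reconstructable from the skeleton unchanged. Genuine branches extend
beyond the calibre of their neighbours and are never eligible; components
that are pure endpoint-to-endpoint paths are never pruned. Pruning and
re-thinning repeat until stable. `prune_spurs = FALSE` exposes the raw
thinning output.

**Local radius.** The default radius estimate at a skeleton voxel is the
EDT value — the physical distance to the nearest background voxel, with the
volume border counting as background. An alternative `radius_mode =
"peel_iterations"` records the chessboard (26-neighbourhood) peel count, the
literal number of onion layers removed before the voxel became central;
`average_thickness()` converts peels to mm by the mean neighbour distance.
The EDT default is preferred because peel counts depend on the thinning
schedule and ignore anisotropy, while the EDT is rotation-robust and in mm
natively.

## Stage 3: classification and the seven characteristics

Every skeleton voxel is classified by its number of 26-connected skeleton
neighbours: isolated (0), endpoint (1), vessel point (2), bifurcation point
(3), crossing point (4), cluster (≥ 5). Isolated voxels and clusters are
treated as PD noise or scanning artefacts (clusters typically arise from
skeletonizing hollow signal) and are excluded from every downstream
quantity; the per-stage logs report how many voxels were excluded, since
this is otherwise invisible.

Neighbour counting uses the full skeleton *before* exclusions; excluded
voxels are then removed from the traversal graph, so a vessel run that abuts
a cluster terminates there rather than acquiring fabricated connectivity
through noise. Voxels with exactly 4 neighbours are always "crossing": no
geometric test distinguishes a true 4-way crossing from two near-tangent
vessels, and the class is defined purely by neighbour count.

With `d̄` the mean centre-to-centre distance over all unordered 26-adjacent
skeleton voxel pairs (a per-scan quantity, computed from physical spacing):

* **total network length** = (endpoints + vessel + bifurcation + crossing
  points) × d̄. This voxel-count form overestimates an open chain's
  geometric length by about one step per chain (a ~10 % effect on typical
  phantoms); an alternative `length_mode = "edge_sum"` sums true distances
  over adjacent included pairs for users who prefer the unbiased estimate.
* **average vessel length** = (mean number of interior vessel points per
  segment) × d̄, where segments are maximal vessel-point runs between
  endpoint/bifurcation/crossing nodes. Two directly adjacent nodes
  contribute a zero-interior segment; a closed all-vessel loop — anatomically
  expected where anastomoses form — is one segment flagged cyclic, with the
  component size as its interior count. With no segments the quantity is
  undefined and reported as `NaN`, never 0.
* **average thickness** = mean local radius over included voxels (per-voxel
  averaging; a per-segment average would weight short segments up without a
  correspondingly clear interpretation).

All means are plain sums over enumerated voxels or segments, so results do
not depend on enumeration order.

## Phantoms: what they emulate and what they do not

`phantom_spec()` describes a vascular phantom as a spatial graph — nodes at
physical positions, edges with a tube radius — rasterized as a union of
capsules. Ground truth (endpoint/bifurcation/crossing counts, exact
centerline length, component count) is derived from the graph alone, never
from the voxelization, so recovery tests cannot be circular.

The random tree generator (`phantom_tree()`) defines the package's
documented *clean family*: arm radius ≥ 3 voxels, arm length ≥ 10 voxel
steps (drawn ±20 % around `arm_length = 14`), arms along 26-neighbourhood
lattice directions, the three directions at each junction pairwise
non-adjacent as lattice offsets and no two of them coplanar in an
axis-aligned plane, daughters diverging at least ~41° from the stem,
non-adjacent arms separated by at least two tube diameters plus two voxels,
and a spherical bulge of radius + 2 voxels painted at each branch node (the
dilated confluence of real junctions; it gives the distance transform a
unique maximum at the node so the junction thins to a single voxel). On this
family `characterize()` recovers endpoint and bifurcation counts exactly —
verified in the test suite across trees with 0, 1, 2 and 5 bifurcations —
and a broad internal sweep of 100 random trees reproduced the topology in
99 of 100 cases, the exception being a junction rendered as two adjacent
bifurcation voxels. Outside the clean family (thinner tubes, grazing arms,
slowly diverging junctions) discretization can split junctions or merge
arms, which is the expected behaviour of voxel skeletons, not a pipeline
defect.

Artefact injection (`add_artifacts()`) adds one-voxel-thick supra-threshold
stripe planes (mimicking the stripe-like PD artefacts of clinical scans),
small solid blobs that skeletonize into clusters, and isolated
supra-threshold voxels — enough to exercise the exclusion logic. The
phantoms do not attempt physical realism: no speckle statistics, no
attenuation, no flow-dependent intensity. Passing phantom tests therefore
demonstrates the geometry/topology machinery, not robustness to real
acquisition physics; on clinical data the manual region segmentation and
artefact erasure remain the guard against the latter.

## The synthetic cohort

`synth_cohort()` emulates a longitudinal first-trimester study: visits
scheduled at 7, 9 and 11 weeks gestational age (GA, jittered with SD 0.3
weeks), a binary placenta-related complication flag with prevalence 0.25,
and covariates with realistic prevalences (57 % nulliparous, 41 % IVF/ICSI
conceptions, 50 % male foetuses). Each variable follows a quadratic-in-GA
trajectory with a subject random intercept. Two noise models:

* `"lognormal"` (default, the study condition): the model lives on the log
  scale, giving positive right-skewed characteristics; the complication
  stratum is scaled by a multiplicative `effect` (default 1; 0.85 emulates
  the ~10–15 % deficit in counts seen in affected pregnancies). Subject
  intercepts share a latent factor (`cor_subject = 0.7`) so characteristics
  are strongly mutually rank-correlated, as they are in real cohorts.
* `"gaussian"`: the identical structure applied additively on the response
  scale — the exact generating process of the linear mixed model below,
  used for parameter-recovery and type-I-error simulations.

Default trajectory magnitudes (counts in the low hundreds at 9 weeks,
roughly doubling from 7 to 9 weeks; PV and uPVV growing faster than the
skeleton so density ratios fall with GA) were chosen once as representative
first-trimester values and are documented in `cohort_growth_defaults()`.

## Cohort statistics

* **Spearman matrices** use midrank ties via `stats::cor.test`; constant
  variables yield flagged `NA`, never a fabricated coefficient.
* **PCA** standardizes variables (correlation-matrix PCA) before
  eigendecomposition. The choice is deliberate: the characteristics span
  orders of magnitude (vessel-point counts in the hundreds vs thicknesses
  of ~1 mm), and covariance-matrix PCA would let the count scale dominate
  PC1 trivially. Sign convention: each component's largest-magnitude
  loading is positive. Explained-variance fractions sum to 1.
* **Mann–Whitney U** uses the exact null distribution for combined n ≤ 20
  without ties, else the normal approximation with tie and continuity
  correction (`stats::wilcox.test`); the exact branch is verified against
  full enumeration of all group assignments in the test suite.
* **Linear mixed models** (`lme4`) fit `value ~ GA + GA² + (1 | subject)`
  by maximum likelihood — not REML — so that the covariate-interaction
  block (main effect + GA and GA² interactions, 3 df) can be tested by a
  likelihood-ratio test between nested fits. Non-convergence is surfaced as
  a warning and recorded in the fit object, never ignored. For the
  right-skewed characteristics `log_scale = TRUE` fits the log response.
* **Per-week comparisons** assign each visit to the nearest scheduled week
  within ±1 week; other visits are excluded from that comparison. No
  multiplicity correction is applied in the primary tables (each p-value is
  read at the 0.05 level); `adjust_comparison()` adds Benjamini–Hochberg
  adjusted values for users who want FDR control.

## Numerical and degenerate-input conventions

* Arrays are `dim = c(nx, ny, nz)`, x fastest; voxel indices 0-based in
  coordinate tables; voxel centers at `(i·sx, j·sy, k·sz)` mm. The volume
  border counts as background for distance transforms.
* Empty selection → empty skeleton, zero counts, zero total length,
  `NaN` averages (with warnings). Zero ratio denominators → `NA` with a
  warning, never 0. Empty masks are legal but warned about.
* Intensities outside \[0, 255\] are an error, never clamped.
* All phantom and cohort randomness sits behind explicit integer seeds;
  identical seeds give identical output to the bit.

## Problem sizes used in the validation suite

The test suite and the reproduction script run tube/Y/tree phantoms on
grids of roughly 40–90 voxels per side (thousands to tens of thousands of
foreground voxels), classification oracles on 100 random voxel sets up to
20³, exact Mann–Whitney enumeration up to combined n = 12, and mixed-model
simulations with 200 replicates of 200 subjects × 3 visits. These sizes
give stable estimates (binomial SE on the type-I rate ≈ 0.015 at 200
replicates) while keeping a full run in the low minutes on a single core;
clinical volumes an order of magnitude larger process in seconds each
through the same compiled core.

## Known limitations

* Junction rendering in voxel skeletons is not perfectly canonical: a
  branch node can, in rare unfavourable geometry, appear as two adjacent
  3-neighbour voxels and inflate the bifurcation count by one pair. The
  clean phantom family constrains geometry to make this vanishingly rare;
  on clinical data it is an inherent property of neighbour-count
  classification.
* The voxel-count total-length formula carries a known upward bias
  (~one d̄ per open chain and extra steps across widened junctions); the
  `edge_sum` mode quantifies it per scan.
* Maternal and embryonic/foetal vessels cannot be distinguished from PD
  signal alone; the characteristics describe the combined network.
* The cohort simulator is a statistical emulation for validating the
  analysis code, not a biological model; effect sizes recovered from it
  validate the estimators, not any physiological claim.
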