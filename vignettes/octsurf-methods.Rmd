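---
title: "Graph-based intraretinal surface segmentation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based intraretinal surface segmentation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsurf)
```

## The problem

Macular SD-OCT volumes resolve the retina into alternating bright and
dark bands whose interfaces — the intraretinal surfaces — carry the
clinically relevant thickness measures: the ganglion cell complex
(GCC, ILM to IPL-INL) for glaucoma, and the total retina (ILM to the
inner RPE surface) on the ETDRS grid for macular disease.  Slice-wise
segmentation fails where the signal does: vessel shadows, focal
dropout, and speckle can erase an interface in a single B-scan while
it remains obvious in the adjacent ones.  `octsurf` therefore treats
segmentation as a *global* optimization over the full 3-D volume:
each surface is the exact minimizer of a cost over every column
simultaneously, subject to hard geometric constraints.

## The surface model

A surface assigns one axial index $z(x,y)$ to every A-scan column.
Feasibility imposes:

* **smoothness** — $|z(x,y) - z(x',y')| \le \delta_{x}$ (or
  $\delta_{y}$) for 4-neighbor columns;
* **search region** — $z_{lo}(x,y) \le z(x,y) \le z_{hi}(x,y)$;
* **separation** — consecutive surfaces must be at least `min_gap`
  voxels apart.

The per-voxel cost is the signed axial intensity gradient (central
differences; one-sided at the axial borders), oriented by each
surface's polarity: $c = -g$ for dark-to-bright interfaces, $c = +g$
for bright-to-dark, $c = -|g|$ where the band contrast is unreliable
(GCL-IPL, Verhoeff's membrane).  The polarity map follows standard
OCT band appearance and is configurable.  The cost is invariant to
intensity offsets and positively homogeneous under intensity scaling,
so exposure differences do not move the optimum.

### Minimum closed set

The minimum-cost feasible surface is found exactly by the closure
reduction.  Each in-region voxel becomes a graph node with weight

$$ w(x,y,z) = c(x,y,z) - c(x,y,z-1), \qquad
   w(x,y,z_{lo}) = c(x,y,z_{lo}) - \Omega, $$

with $\Omega = 1 + \sum |c|$ so that every column contributes exactly
one surface voxel.  Closure arcs run down-column
($(x,y,z) \to (x,y,z-1)$) and to each 4-neighbor column at
$(x',y',\max(z'_{lo}, z-\delta))$, encoding the smoothness constraint
exactly.  A *closed set* (one containing every successor of each
member) then corresponds one-to-one to a feasible surface — the
surface is the per-column maximum of the set — and its weight
telescopes to the surface cost, so the minimum-weight closed set is
the globally optimal surface.

The minimum closed set is computed by the standard max-flow
transformation (source to negative nodes, positive nodes to sink,
closure arcs effectively unbounded) with a compact Dinic max-flow in
C++ (`src/maxflow.cpp`).  Among all minimum closed sets the package
returns the *minimal* one — the residual reachability of the source —
which is unique.  Two consequences matter in practice:

* **determinism** — identical inputs give bit-identical surfaces, and
  on cost ties the lowest-z surface is returned;
* **exactness** — the result provably attains the global minimum,
  which the test suite verifies against exhaustive enumeration
  (closed sets of random DAGs; all feasible surfaces of small cost
  volumes) and against an independent max-flow route via `igraph`.

Before solving, search regions are tightened to a fixpoint under the
couplings $z_{hi}(p) \le z_{hi}(q) + \delta$ and
$z_{lo}(p) \ge z_{lo}(q) - \delta$; an empty region after tightening
is reported with the offending column pair.

## Multi-resolution, multi-surface strategy

Four pyramid levels are built by factor-2 axial block averaging (the
ceiling convention keeps the deepest samples; x and y resolution is
never reduced).  Each surface is detected coarse-to-fine: at the
coarsest usable level over its whole admissible band, then at each
finer level within `refine_margin` (default 5) voxels of the
upsampled coarser solution.  Smoothness deltas scale as
$\max(1, \mathrm{round}(\delta/2^l))$.

The eleven surfaces are detected sequentially, each restricted
between already-finalized surfaces with a minimum separation of
2 voxels.  The default order is ILM, IS-OS, RPE/BM, OS-RPE, VM,
OPL-ONL, ONL-IS, INL-OPL, NFL-GCL, IPL-INL, GCL-IPL: high-contrast
interfaces first, so that at every step the target is the strongest
correctly-signed edge *within its admissible band*.  (Detecting
OS-RPE before RPE/BM, for example, would lock onto the stronger
RPE/BM edge; the order is configurable.)

Three numerical details make the coarse levels trustworthy:

* **conservative rounding** — a coarse voxel is searchable only if
  its whole fine z-block lies inside the admissible band, so an
  excluded neighbor edge cannot re-enter at coarse scale;
* **stencil clearance** — at interior band edges the admissible range
  is shrunk further so that the blocks read by the central-difference
  stencil are clear of the finalized neighbor's intensity step, which
  block averaging would otherwise smear into the coarse costs;
* **pinning** — columns whose band is narrower than one coarse voxel
  (e.g. where the foveal pit squeezes the inner layers to nothing)
  are pinned to the band midpoint at that level and resolved at finer
  levels.

The minimum separation of 2 voxels (not 1) keeps the $\pm$1-voxel
central-difference response of an already-finalized edge out of the
next surface's band; with a 1-voxel gap the weak GCL-IPL interface
reproducibly snaps onto the NFL-GCL response.

### Smoothness defaults

A fixed voxel delta is not transferable across scan geometries, so
deltas derive from a maximum anatomical slope (mm of depth per mm of
lateral travel) times the lateral/axial spacing ratio, with a floor
of 2 voxels; for the reference 512 x 128 x 885 geometry over
6 x 6 x 2.3 mm this reproduces 2 voxels in both lateral directions.
Slopes are graded per surface (`default_surface_slopes()`): 0.25 for
the ILM, which carries the full foveal pit wall, decreasing through
the inner surfaces to 0.05 for the outer photoreceptor/RPE complex,
which is nearly flat.  The grading matters under heavy speckle: a
single loose delta sized for the pit lets the flat outer surfaces
jitter column-to-column, and tightening them roughly halved the
pooled phantom error in development.

## Preprocessing

Speckle is reduced by the modified curvature diffusion equation:
mean-curvature flow modulated by the conductance
$g(|\nabla I|) = \exp(-(|\nabla I|/\kappa)^2)$, explicit scheme,
central differences in voxel units, time step 1/16 (the 3-D stability
bound).  Planar layer boundaries have near-zero mean curvature and do
not move; per-voxel speckle has high curvature and is flattened.  The
threshold $\kappa$ is expressed as a multiple (default 2.0) of the
image's mean gradient magnitude, recomputed each iteration, making
the parameter invariant to the intensity scale — an absolute
threshold would silently disable diffusion on 8-bit-range data.  The
filter default is 5 iterations; the noisy-phantom pipeline in the
tests and acceptance script uses 30, where accuracy plateaus (more
iterations neither help nor harm within the tested range).

## Thickness and the ETDRS grid

Thickness is the axial index difference times the axial spacing
(reported in micrometres), matching the axial-distance convention of
commercial OCT; no surface-normal correction is applied.  Composites:
RNFL (surfaces 1-2), GCL+IPL (2-4), GCC (1-4), total retina (1-9 —
the inner RPE surface, not Bruch's membrane).  Thickness telescopes
exactly: `t(i,j) + t(j,k) = t(i,k)`.

The fovea is the deepest point of the ILM (largest z), located after
median smoothing (radius 3 pixels) within a central 3-mm window —
the raw argmax is degenerate under speckle — with exact ties resolved
to the centroid of the tied set.  The ETDRS grid centers there:
radial intervals are half-open ($r \le 0.5$ mm Cen;
$0.5 < r \le 1.5$ inner ring; $1.5 < r \le 3$ outer ring, pixel-center
geometry), rings split into quadrants by the $\pm 45^\circ$
diagonals, diagonal ties going to the vertical (S/I) quadrants; the
nine sectors therefore partition the 6-mm disc exactly, with no pixel
counted twice.  Nasal/temporal follow laterality (OD: nasal is the
$-x$ direction by default) and the superior end of the y axis must
come from scan metadata (`y_superior`).  `Ave` is the mean over the
whole 6-mm disc — equivalently the pixel-count-weighted mean of the
nine sector means — rather than their unweighted average.  A sector
with no pixels inside the footprint is reported as missing, never as
zero.

## Agreement statistics

`bland_altman()` reports the paired bias, the SD of the differences
(n−1 denominator), the conventional 95% limits of agreement
bias $\pm\ 1.96 \cdot$ SD, and their span $3.92 \cdot$ SD.  The
coefficient 1.96 (not a t-quantile) matches conventional
Bland-Altman practice.  The p-value is a two-sided paired t-test; a
sign-flip permutation test is available as a configuration
alternative.  When all differences are identical the t statistic is
undefined and the degenerate limits are used (p = 1 for zero bias,
else 0).  The report formatter rounds means and differences to one
decimal and r to two, so the printed mean difference always equals
the difference of the printed group means up to at most 0.15 (three
cells each rounded at 0.05).  The bundled reference table
(`inst/extdata/reported_agreement_tables.csv`, summary statistics
from a published clinical comparison of a commercial built-in
algorithm with a graph-based algorithm) satisfies that identity in
25 of its 26 rows; the one exception (sector Ave, glaucoma group,
printed difference 1.0 vs 251.4 − 250.7 = 0.7) is pinned explicitly
in the test suite as a data-integrity finding.

## The phantom

`phantom_spec()`/`generate_phantom()` produce a macula-centered
volume with known truth, so segmentation accuracy is measurable
without clinical data.  The defaults model a 6 x 6 mm field on a
64 x 32 lateral grid with 128 axial samples at the native axial
resolution of the reference geometry (2.3/885 mm per voxel, a 0.33 mm
axial window containing the retina):

* eleven interfaces at fixed base depths with a shared smooth
  undulation field (sum of three seeded low-frequency cosines,
  amplitude 8 um, correlation length 1.5 mm — bandlimited, so
  feasibility under the default smoothness deltas is checked and
  holds at generation time);
* a foveal pit (cosine bump, radius 1 mm, ILM dip 120 um) that pulls
  surfaces 1-6 toward the OPL-ONL floor, thinning the inner layers to
  near zero centrally without ever crossing;
* twelve per-region intensity bands consistent with the polarity
  table (vitreous dark, RNFL bright, alternating inner bands, bright
  IS/OS and RPE, dark choroid);
* unit-mean multiplicative gamma speckle (default shape 4, i.e.
  SD = 50% of the local mean), additive Gaussian noise (SD 2), and 3
  vessel-shadow bands (2 voxels wide) attenuating everything below
  the NFL-GCL surface by half.

A surface index marks the deepest voxel above its interface, so the
noiseless central-difference response (which ties across the two
voxels flanking the step) resolves onto the truth under the
lowest-z tie-break.

What the phantom does *not* emulate: the scanner point-spread
function and depth-dependent attenuation, motion and rotation
artifacts between B-scans, retinal curvature at the 6-mm scale,
pathology (drusen, edema, layer dropout).  Passing the phantom tests
therefore demonstrates the correctness of the optimization and the
robustness of the pipeline to speckle and shadows — not clinical
accuracy on diseased eyes.

## Problem sizes and runtime choices

The test suite and acceptance script use: exhaustive closed-set
enumeration on 100 DAGs of up to 12 nodes; brute-force product-space
search on 200 cost volumes up to 4 x 3 x 6 with deltas 0-2; phantom
recovery at 64 x 32 x 128 (noise-free and degraded); determinism and
end-to-end runs at 24 x 12 x 96 and 16 x 8 x 64.  These sizes keep
every exact oracle exact and the full suite in well under a minute of
solver time while exercising all code paths; the solver itself
handles the reference 512 x 128 x 885 geometry, whose coarse level is
comparable to the phantom's full resolution.

## Known limitations

* Surfaces are detected sequentially, not as a simultaneously coupled
  multi-surface graph; with the banded search this is exact per step
  but could in principle propagate an early error into later bands.
* Hard smoothness constraints only; no soft penalty, so within
  $\pm\delta$ the surface follows the cost unregularized.
* The GCL-IPL interface has the weakest contrast of the eleven and
  dominates the residual error under heavy speckle.
* Thickness is axial, not normal to the RPE; at the 6-mm field edge
  the difference is small but nonzero.
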