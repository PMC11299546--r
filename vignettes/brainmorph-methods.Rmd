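---
title: "Computational morphometry with brainmorph: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational morphometry with brainmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`brainmorph` is a compact, fully testable implementation of the standard
computational-anatomy workflow for T1-weighted structural MRI: voxel-based
morphometry (VBM) on modulated, spatially registered grey-matter maps,
surface-based morphometry (SBM) on projection-based cortical thickness and
folding measures, and region-based morphometry (RBM) on atlas summaries,
with threshold-free cluster enhancement (TFCE) permutation inference and
retrospective quality ratings. Every stage can be exercised against exact
ground truth from a bundled synthetic phantom generator, so the package's
correctness claims are testable on any machine without external data.

This vignette records the models behind each stage, the tunable parameters
with their defaults and units, the numerical choices, and the design
decisions that were genuinely open — in enough detail that a maintainer can
predict the package's behaviour without reading the sources.

## The phantom generator: what it emulates and what it does not

All validation rests on a star-shaped "cortex" phantom: a white-matter (WM)
core whose radius is modulated by a smooth angular folding term

$$ r(\theta, \varphi) = R + A \sin(f\theta)\,\sin(f\varphi), $$

wrapped in a grey-matter (GM) shell of constant normal thickness $t$ and a
cerebrospinal-fluid (CSF) shell, imaged as the fraction-weighted mixture of
three tissue intensities, multiplied by a smooth multiplicative bias field
and corrupted by Gaussian noise. The noise convention follows the simulated
brain-MRI standard: `noise_percent` is the noise standard deviation as a
percentage of the brightest-tissue (WM) mean, and the bundled evaluations
sweep 1–9% in that convention. Gaussian (not Rician) noise is used: at
these signal levels the Rician distribution is near-Gaussian, and the
Gaussian choice keeps the generator's sigma an exact oracle for the noise
estimator.

Key constructive choices:

* **Constant normal thickness.** The signed distance to the folded WM
  surface is computed analytically as
  $(\rho - r(\theta,\varphi)) / \sqrt{1 + |\nabla_s r|^2/\rho^2}$, the
  radial gap divided by the local surface slant. This is exact for
  unfolded spheres and first-order accurate near the surface otherwise, so
  the GM shell has (to that order) constant thickness $t$ — an analytic
  ground truth for the thickness pipeline that survives folding.
* **Partial-volume fractions by supersampling.** Each voxel is subdivided
  3×3×3 and the analytic tissue label evaluated at the 27 sub-centres;
  fractions are therefore quantised in units of 1/27 (≤ 2% fraction
  error, which several tests account for).
* **Bias field.** The lowest-order separable polynomial
  $(1 + x/2)(1 + y/2)(1 + z/2)$ in normalised coordinates, rescaled so its
  peak-to-peak amplitude equals `bias_percent`.
* **Cohorts.** `generateCohort()` plants a pure thickness effect: group B
  phantoms have `gm_thickness` reduced by `atrophy_percent`; every subject
  additionally receives seeded jitter on the WM radius (sd 0.3 mm) and
  multiplicative intensity jitter (sd 2%). These two jitter scales are the
  package's notion of anatomical and scanner variability at desk scale; no
  claim is made that they match any particular scanner.

What the phantom does *not* emulate: skull and non-brain tissue, Rician
noise floors, motion or ghosting artifacts, multi-coil inhomogeneity
patterns, real gyral geometry (folding here is a smooth low-frequency
perturbation), or topological defects. Tests passing on phantoms therefore
validate the numerics and the contracts of each stage — sub-voxel boundary
placement, conservation under modulation, FWE calibration — not robustness
to real-scanner pathology.

All generation is a pure function of the spec (seeded, bit-identical
reruns); grids default to 48³ voxels at 1 mm.

## Denoising: spatially adaptive non-local means

Local noise is estimated from Laplacian pseudo-residuals
$r = (I - \bar I_6)/\sqrt{1 + 1/6}$ (six-neighbour mean), aggregated as a
sliding-window root mean square (window half-width 2 voxels). Tissue
structure would inflate this estimate, so voxels whose gradient magnitude
exceeds 2.5× the current sigma estimate are excluded and the threshold is
iterated to a fixed point (at most 4 passes); on a noiseless image the
estimate collapses to zero instead of reporting edge energy as noise. The
exact adaptivity rule of the original filter is not public; this explicit
estimator is the package's definition, and it is what the tests pin down.

The filter itself is blockwise non-local means with 3³ patches, a 7³
search window and weights
$\exp(-\lVert \Delta P \rVert^2 / (2\beta\sigma_{\mathrm{local}}^2 |P|))$,
$\beta = 1$ by default. The output is a convex combination of input
values, hence never leaves the input range. Rician correction is omitted
(phantom noise is Gaussian); this is a documented limitation for real
data.

## Tissue segmentation: AMAP with MRF and partial-volume estimation

Segmentation is intensity-driven and uses no atlas priors, so it is
equivariant under axis flips (a property test). Components:

* **Initialisation.** Three-class k-means with deterministic quantile
  seeding (centres at the 1/6, 3/6, 5/6 intensity quantiles); cluster
  *medians* are reported as initial means because medians resist the
  partial-volume tails.
* **AMAP iterations.** ICM/EM hybrid: the E-step scores each voxel by the
  Gaussian log-likelihood plus a Potts prior `mrf_beta` (default 0.1) times
  the count of same-label 6-neighbours; the M-step re-estimates class
  variances from posteriors and the class means from high-confidence
  voxels (posterior ≥ 0.9) only. Intensity inhomogeneity is handled by a
  single smooth multiplicative gain field shared by the three classes:
  each class's intensity-to-mean ratio is Gaussian-smoothed (24 mm FWHM,
  `adapt_fwhm_mm`), the classes are pooled by local support, and the gain
  accumulates multiplicatively across iterations. One smoothing pass on a
  desk-scale object underestimates the field's amplitude; the
  multiplicative accumulation converges to the full amplitude because the
  smoothed *residual* ratio tends to 1. A shared gain (rather than three
  independent local mean fields) keeps the class means coherent where a
  class is thin or absent — the thin GM shell of the phantom made
  independent per-class fields actively harmful. Iterations stop when
  fewer than 0.1% of labels change (at most `iters`, default 16).
* **Partial-volume estimation.** Voxels are reassigned on the continuous
  1–3 label scale among {CSF, CSF/GM, GM, GM/WM, WM}: the mixed fraction
  of the brighter tissue is $(I - m_{low})/(m_{high} - m_{low})$ under the
  local (gain-corrected) means, clipped to [0, 1]; mixed labels are only
  allowed where both parent tissues appear in the 6-neighbourhood, and
  `gm_fraction = 1 - |pve - 2|`. The PVE boundary is therefore placed
  where the interpolated tissue fraction crosses one half, which is what
  the surface stream relies on.
* **Local intensity transformation.** A voxel-wise monotone
  piecewise-linear map sends the local CSF/GM/WM means to 1/3, 2/3 and 1,
  flattening intensity inhomogeneity before surface processing.

Accuracy is scored as Cohen's kappa of one tissue against ground truth.
On the bundled evaluations the full pipeline (SANLM + AMAP + PVE) reaches
GM kappa 1.00 on the noiseless shell phantom, stays above the plain
pipeline (no denoising, no PVE) at every noise level 1–9%, with the
largest margin at 9% — the adaptive combination pays off most for noisy
data. The bias benefit of the adaptive gain is demonstrated on the
PVE-refined output under a pure-bias (noiseless, 10% peak-to-peak)
condition; with noise present the bias effect on a desk-scale phantom is
smaller than the noise effect and the comparison is uninformative either
way.

## Registration, modulation and templates

Pairwise registration is multi-resolution (3 levels) stationary-velocity
demons: a moment-based pre-alignment (translation + isotropic scale; no
rotation — phantom cohorts are axis-aligned, a documented limitation for
real data), then per level a demons force update capped at half a voxel,
Gaussian regularisation of the velocity field (`smooth_mm`, default 6 mm
FWHM), and exponentiation by scaling-and-squaring — which guarantees a
diffeomorphism; the Jacobian determinant is checked positive after every
registration. Warping is pull-back trilinear interpolation (nearest
neighbour enforced for label volumes), and VBM modulation multiplies the
warped tissue map by the Jacobian so compartment volumes are conserved
(within 1% on interior-supported phantoms). Templates are built by
iterated register-and-average (default 3 iterations); the template's mean
gradient magnitude — its sharpness — exceeds that of the naive average on
jittered cohorts.

The deformation-field convention everywhere: `T(x) = x + d(x)` in world
mm on the reference grid, with `warpVolume(moving, field)` sampling
`moving` at `T(x)`, so registration returns the field that carries the
moving image onto the fixed one.

## Cortical thickness: distances, projection, surfaces

* **Boundary distances.** The WM and brain (GM+WM) fraction fields are
  triangulated at their 0.5 level by marching tetrahedra; the interface
  mesh receives 10 iterations of shrink-free (Taubin) smoothing to remove
  tessellation bumps (which would bias minimum distances short), and every
  voxel centre in a band around the interface takes its exact Euclidean
  point-to-triangle distance. This realises "the boundary sits where the
  tissue fraction crosses one half" with sub-voxel accuracy: on the
  10/14 mm shell the mean of `wmd + csfd` over GM is within 0.04 mm of the
  true 4 mm.
* **Projection-based thickness.** Thickness candidates `wmd + csfd` are
  seeded at the outer GM boundary (voxels with `csfd` below one voxel) and
  max-propagated inward along non-increasing WM distance over the
  26-neighbourhood, accepting a candidate only if it does not exceed the
  voxel's own `wmd + csfd`. Plateau (equal-`wmd`) moves are allowed so
  estimates travel along iso-distance bands — necessary where a sulcus is
  blurred only in part. Blurred sulci thus inherit the banks' thickness
  instead of the doubled naive value (a constructed two-slab test pins
  this down). The propagation is iterated to a fixed point (error after
  100 sweeps).
* **Central surface.** The level function `wmd − thickness/2` (signed
  through WM, thickness extended a few voxels beyond GM by neighbour
  means) is triangulated at zero by marching tetrahedra; cleanup keeps the
  largest component and fans any boundary loops; the Euler characteristic
  and genus are reported on the mesh record (genus 0 expected on
  phantoms; no spherical-harmonic topology repair is attempted). White
  and pial meshes share the central topology, offset along the level
  gradient by ±thickness/2; the central surface lies strictly between
  them.
* **Refined thickness.** The surface-based metric
  $T = \tfrac12[d(\mathrm{white} \to \mathrm{pial\ surface}) +
  d(\mathrm{pial} \to \mathrm{white\ surface})]$ with exact
  point-to-triangle distances; concentric-sphere meshes recover their gap
  within 1%.
* **Depth sampling.** `sampleToSurface()` samples a volume at a relative
  depth α along the vertex normal: equidistant
  ($r_{white} + \alpha T$) or equi-volume, which in the local spherical
  approximation (radius from the mean curvature) samples at
  $((1-\alpha) r_{in}^3 + \alpha r_{out}^3)^{1/3}$ so the cortical volume
  fractions above and below the sample survive folding; it reduces to the
  equidistant rule on flat cortex and reproduces the closed-form shell
  value 12.24 mm at α = 0.5 on the 10/14 shell.
* **Surface smoothing.** Iterated symmetric neighbour diffusion with edge
  weights $\min(a_i/\deg_i, a_j/\deg_j)$ — exactly conservative for the
  area-weighted mean and stable on meshes with degenerate vertices. The
  iteration count and step size are calibrated from the mesh's edge-length
  statistics so an impulse attains the requested geodesic FWHM (measured
  within 15%; in practice within ~1% on regular meshes). Default
  smoothing: 6 mm FWHM for volume maps, 12 mm for surface scalars.

Thickness estimates are consistent across acquisition resolution: the same
shell regenerated at 1.0/0.8/0.7 mm changes mean thickness by well under
5%.

## Folding metrics

* **Gyrification** — absolute mean curvature |H| (1/mm) from the cotangent
  Laplace–Beltrami mean-curvature normal with barycentric vertex areas,
  averaged over a 3 mm neighbourhood (the neighbourhood scale is this
  package's choice; it is exposed). Spheres give 1/r within 2%; |H|
  scales as 1/s under uniform scaling.
* **Sulcal depth** — Euclidean distance to the enclosing convex hull,
  evaluated as the minimum over the support planes spanned by the mesh's
  own outward vertex normals. The direction set rotates with the mesh, so
  the measure is exactly invariant under rigid motion; with the phantom
  meshes' ~1 mm vertex spacing the support-plane approximation
  under-resolves the hull by well under 0.1 mm. Zero on convex surfaces; an optional square-root
  transform is off by default.
* **Spherical parameterization** — area-weighted centering and radial
  projection (exact and bijective for star-shaped surfaces, which the
  phantom's central surfaces are), followed by mild tangential Laplacian
  inflation (10 iterations, step 0.2, reprojected each step) and area
  distortion relaxation (60 iterations) in which vertices migrate toward
  regions where the map is expanded. Outputs are checked for flipped
  spherical triangles (none on phantom meshes) and per-vertex area
  distortion (median within [0.5, 2] for folds up to 20% of the radius).
  An already-spherical mesh short-circuits to the pure radial projection.
* **Fractal dimension** — the vertex coordinates are expanded in real
  orthonormal spherical harmonics on the sphere map (area-weighted least
  squares with a tiny ridge), band-limited surfaces are reconstructed at
  even degrees l = 2 … 32, and FD = 2 + slope of log(area) vs log(l) over
  the scaling regime l ∈ [8, 32]; the low-degree regime is excluded as
  trivially smooth, and `l_max` shrinks automatically if the mesh has too
  few vertices to support the basis. Spheres give 2.00 ± 0.05 (areas flat
  in l); FD is scale-free and increases with fold amplitude.
* **Surface ratio** — per-vertex area of the mesh inside a Euclidean ball
  (default radius 20 mm; tests use smaller radii matched to phantom size)
  divided by πr², with boundary triangles clipped by recursive 4-way
  subdivision (depth 3, i.e. 64 sub-triangles). Flat patches give 1;
  the implementation matches a uniform-sampling Monte-Carlo oracle within
  2%.

All four metrics are deterministic, invariant under rigid motion and
vertex reindexing, and all four increase on cohorts with a planted
increase in folding amplitude.

## Statistics: GLM, TFCE, permutation FWE, FDR

Second-level inference is an ordinary least-squares GLM per voxel or
vertex with a single contrast,
$t = c^\top\hat\beta / \sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}$.
TIV is removed from volume data by global scaling (each subject multiplied
by mean(TIV)/TIV); cortical thickness is not TIV-corrected. Nuisance
covariates (e.g. age) are centred and handled under permutation by the
Freedman–Lane scheme: the reduced model's residuals are permuted within
exchangeability blocks and the full model refitted. Group contrasts
default to one-tailed.

TFCE integrates cluster extent^E × height^H over 100 equal threshold steps
up to the map maximum (defaults E = 0.5, H = 2 on 3-D grids with
26-connectivity; E = 1, H = 2 on meshes, where extent is the member vertex
area). The implementation processes thresholds from high to low with a
union–find over the adjacency, and matches a brute-force per-threshold
component-labelling oracle to machine precision; on a fixed threshold grid
it is monotone in every input value (raising a value above the previous
map maximum rescales the grid, so strict monotonicity is stated for
perturbations below the maximum). Family-wise error is controlled by the permutation
distribution of the maximum TFCE value,
$p(v) = (1 + \#\{\max^{perm} \ge \mathrm{TFCE}(v)\})/(n_{perm}+1)$; when
fewer distinct within-block permutations exist than requested they are
enumerated exactly and the result notes exactness. On 200 null cohorts
(n = 10/10, 1000-voxel maps, 99 permutations) the empirical FWE sits
inside the binomial 95% interval around 0.05, and a planted 20% atrophy
cohort yields significant voxels inside the planted GM region. Regional
tables are corrected by Benjamini–Hochberg FDR (via `p.adjust`), checked
against an exhaustive step-up oracle.

## Quality control

Three measures, each mapped linearly onto a 0.5–10.5 rating scale between
anchors and graded A+…F: noise-to-contrast (sd of pure-WM residuals about
the smooth WM mean field, over the GM–WM contrast; anchors 0 → 0.5,
0.5 → 10.5), inhomogeneity-to-contrast (sd of the smooth WM mean field
over the contrast; same anchors), and resolution (RMS voxel size; anchors
0.5 mm → 0.5, 3 mm → 10.5). The anchors are package choices — the
published scale concept does not state them — so the tests guard
*monotonicity* of each rating in its degradation parameter rather than
absolute values; the overall rating is the (2,1,1)-weighted mean favouring
noise, and a pristine 1 mm phantom grades A. Cohort homogeneity is the
correlation of each subject's registered, smoothed GM map with the
leave-one-out mean, standardised as z = scale(1 − r), flagging |z| > 2;
a planted doubled-thickness outlier receives the maximum z.

## Region-based morphometry

Atlases are integer label volumes (or per-vertex codes) with a lookup
table; warping into native space is nearest-neighbour pull-back, which can
only lose, never invent, codes. Regional GM/WM/CSF volumes are fraction
sums times the voxel volume — exactly additive under region merging and
conserved against whole-brain totals — and regional thickness is the
area-weighted vertex mean (vertex area = one third of incident face
areas). No atlas ships with the package; tests build toy atlases in code.

## Pipeline orchestration and problem sizes

`runSubject()` executes denoise → segment (→ register when a template is
given) and, only if the voxel stream succeeded, the surface stream;
failures abort with the stage name and keep completed outputs.
`runStudy()` processes a cohort, builds a GM template, warps, modulates
and smooths each subject's GM map, then runs the TFCE permutation group
comparison and (with an atlas) the FDR-corrected regional table, plus the
homogeneity screen. A `longitudinal` flag is reserved and errors: only the
cross-sectional stream is implemented.

The bundled evaluations run on 36–56³ phantom grids, cohorts of 4–20
subjects, 99 permutations for single power checks and 200 simulations for
the FWE calibration. These sizes were chosen so the entire evaluation
executes on a single CPU in well under half an hour while every tolerance
stated above remains binding; all of them scale up by changing the spec
objects only.

## Known limitations

* No skull stripping, no Rician noise model, no motion/artifact
  detectors: real scanner data would need preprocessing before this
  pipeline.
* Registration pre-alignment has no rotation component.
* Topology repair is component/hole cleanup with genus reporting, not
  spherical-harmonic reconstruction; meshes with handles are reported,
  not repaired.
* The spherical parameterization is designed for near-star-shaped
  surfaces; deeply folded real cortices would need a stronger scheme.
* The PVE model is two-tissue-per-voxel; three-tissue mixtures are
  resolved to the dominant pair.
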