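---
title: "Counting synaptic boutons in 3D: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting synaptic boutons in 3D: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bouton3d)
```

# The problem

Synaptic boutons (microglomeruli) in the insect mushroom-body calyx appear
as bright, roughly spherical puncta of ~1 µm radius after synapsin
immunostaining. Estimating how many there are in a brain region sounds
trivial — threshold, label, count — but three systematic biases make naive
counts wrong by tens of percent:

1. **No single threshold separates all boutons.** Neighbouring boutons fuse
   at low thresholds; dim boutons vanish at high ones.
2. **Axial leakage.** The point spread function plus refractive-index
   mismatch elongates each bouton's image along the optical axis (lateral
   extent ≈ 0.86 µm versus ≈ 3.3 µm axially in the imaging regime this
   package models), so boutons lying above and below a counting volume leak
   signal into it.
3. **Boundary over-counting.** Both manual and automated protocols count
   every bouton that intersects the ROI surface as inside. The excess
   scales with the ROI surface area, so small ROIs (the traditional
   1000 µm³ cube) overestimate density substantially, and linear
   extrapolation of small-ROI counts to a whole region inherits the bias.

`bouton3d` implements the full counting pipeline and the analytic
corrections for biases 2 and 3, plus a synthetic-stack generator with known
ground truth so that every stage is testable without microscope data.

# The counting pipeline

## Deconvolution

Stacks are restored by Richardson–Lucy (RL) iteration, the standard
maximum-likelihood algorithm for Poisson imaging, with the PSF either
measured from sub-resolution fluorescent beads (`measure_psf()`: per-bead
3D Gaussian fits, sigmas averaged across beads) or given parametrically as
per-axis Gaussian sigmas in µm.

Numerical choices that matter:

* **Edge handling.** Convolutions use half-sample symmetric (reflective)
  padding. For a symmetric kernel this makes the blur operator
  self-adjoint and constant-preserving, so the multiplicative RL update is
  an exact EM step and the Poisson negative log-likelihood is
  non-increasing at every iteration — a property the test suite checks on a
  64³ phantom over all 100 iterations. Reflective padding also minimises
  edge ringing, although the pipeline crops the axial margins anyway (see
  below).
* **Iterations.** Fixed at 100 by default, which is sufficient for
  convergence in stacks of this contrast; an optional relative-change
  stopping tolerance (`stop_tol`) is available when reproducibility of the
  iteration count is not required.
* **Order of operations.** Deconvolution runs at the native acquisition
  grid, *then* the stack is resampled to 0.1 µm isotropic voxels
  (trilinear), then 5 µm is cropped from each axial end where deconvolution
  ringing concentrates. RL statistics assume the acquisition grid, which is
  why resampling comes second.

## Multi-threshold segmentation and merging

The core idea: sweep the threshold from 20% to 90% of the global maximum
intensity in steps of 10%. Every bouton appears as a separate 26-connected
component at *some* threshold. For each threshold, objects (connected
components) are extracted with their unweighted voxel centroids and
volumes. Two size filters apply:

* objects **larger than 10 µm³** are removed at *every* threshold (they
  contain multiple fused boutons);
* objects **smaller than 0.05 µm³** are removed at the *lowest* threshold
  only — at higher thresholds genuine boutons legitimately shrink below
  this limit as the threshold eats into them, so the minimum must not be
  applied there.

Object centers closer than **0.8 µm** (strictly) are then linked — within
and across thresholds — and boutons are the connected components of this
proximity graph (single linkage). The bouton center is the arithmetic mean
of its member centroids. The link radius is the one tunable that must be
adjusted to the bouton packing of a new preparation: it has to exceed the
centroid scatter of one bouton across thresholds while staying below
typical nearest-neighbour distances.

Design choices where the method description left room:

* **Connectivity**: 26-neighbourhood, the standard for bright blob
  extraction in 3D. 6-connectivity is available (`connectivity = 6`).
* **Threshold base**: the global maximum of the processed stack, not
  per-ROI maxima, so counts are comparable across ROIs. This is also why
  the method requires *unsaturated* images (`check_saturation()`, default
  tolerance zero): a clipped maximum distorts every threshold below it.
* **Tie-breaks**: thresholding is inclusive (`intensity >= t%`); linkage is
  strict (`distance < 0.8` — a pair at exactly 0.8 µm is not merged).
* **Centroids** are unweighted means of member voxel positions;
  intensity weighting was rejected because it makes centroids drift with
  threshold level, which would inflate the cross-threshold center scatter
  the merge step relies on.

## Count corrections

Counting bouton centers in a half-open ROI box gives the raw count
`N_raw`, which carries both biases described above. They are removed
analytically:

* **Axial leakage** (`correct_axial_leakage()`): boutons within a layer of
  depth `r_leak` above and below the ROI leak into it, so
  `N_corr = N_raw / (1 + 2 r_leak / d_ROI)`, with `d_ROI` the ROI extent
  *along the optical axis* (the cube side, or the slab thickness for a
  non-cubic subregion — this is what gives the 5% correction for a 40 µm
  slab versus 19% for a 10 µm cube). The default `r_leak = 1.16` µm derives
  from the measured size distributions; half the axial-minus-lateral extent
  difference, `(3.3 − 0.86)/2 = 1.22` µm, is offered as an alternative
  (`leak_depth_from_sizes()`) but is *not* the default since the two are
  not identical.
* **Boundary over-counting** (`correct_boundary()`): the affected layer of
  depth `r_mg` (effective bouton radius) on all six faces of a cube gives
  `N_corr = N_raw / (1 + 6 r_mg / d_ROI)`. For non-cubic boxes the surface
  term generalises to `r_mg · 2(ab + bc + ca)/(abc)`
  (`correct_boundary_box()`); the cubic form is the default.

## The count-versus-volume model

Expressing the boundary bias as a function of ROI volume for cubes
(`d_ROI = V^(1/3)`) yields

`N_raw(V) = ρ V + 6 r_mg ρ V^(2/3)`

— a linear term (true count) plus a surface term (over-count).
`fit_boundary_model()` fits both parameters by constrained
Levenberg–Marquardt (`minpack.lm::nls.lm`, `ρ > 0`, `r_mg ≥ 0`; starting
values: `ρ` from the largest volume, where the surface term is weakest, and
`r_mg = 0.43` µm, half the lateral bouton image size). When counts come
from several subjects, they are averaged per volume first and the group
means are fitted unweighted — fitting group means is deliberate: it is how
ROI counts from several animals are combined in practice, and the averaged
counts are what the surface-scaling law describes.

The surface term falls below ~5% of the linear term beyond 10⁵–10⁶ µm³ for
micrometre boutons. Counts taken in a sufficiently large subregion can
therefore be extrapolated linearly to a whole region
(`extrapolate_lip()`, which warns below 10⁵ µm³).

**A known limitation of the fit.** `N_raw(V)` keeps only the leading
surface term of the exact expected intersect-inside count, which for a
cube dilated by a sphere of radius `r` is
`ρ (L³ + 6 r L² + 3π r² L + 4/3 π r³)` (`expected_intersect_count()`).
Fitting the two-term model to counts generated by the full expression
biases `r̂_mg` upward by ≈ 13% at the volume range used here
(10–46.4 µm cube sides), while `ρ̂` stays within ~2%. The tests and the
acceptance script document this: parameter recovery is exact on counts
generated by the two-term model itself, and within 15% (`r_mg`) / 5% (`ρ`)
on geometrically exact simulated counts.

# The synthetic-stack generator

`generate_field()` draws a hard-core point process: bouton count from a
Poisson law with mean `ρ·V`, centers placed by sequential rejection with a
minimum separation (default twice the mean radius, so spheres never
interpenetrate), with an explicit retry cap so infeasible packings fail
loudly. Default radii are 0.9 ± 0.1 µm, i.e. bouton volumes ≈ 3.1 µm³, the
middle of the 2.5–4 µm³ range reported for honey-bee calyx microglomeruli.

`render_stack()` turns a field into an image: solid spheres (axially
stretched by a configurable factor to mimic refractive-index distortion),
convolved with a Gaussian or measured PSF, attenuated by
`exp(−(z − z0)/d)` with depth, optionally multiplied by a compensation
gain following the exponential laser-power ramp
`P(z) = P0 + (Pf − P0)(e^{(z−z0)/d} − 1)/(e^{(zf−z0)/d} − 1)`
(`compensate_power()`; when `Pf/P0 = e^{(zf−z0)/d}` — the
`matched_compensation()` constructor — the ramp is exactly exponential and
cancels the attenuation), then Poisson shot noise at a configurable photon
scale and Gaussian read noise. Each axis must sample the rendered bouton
semi-axis with at least two voxels.

`simulate_roi_counts()` counts boutons per ROI directly on the geometry
under three rules: *intersect-inside* (sphere intersects the box — decided
by the exact closest-point distance, avoiding rasterisation bias; this is
the rule both manual and automated protocols implement and the source of
the boundary bias), *center-inside* (unbiased; expectation `ρV`), and
*majority-inside* (more than half the sphere volume inside, by seeded
Monte-Carlo with 10⁴ samples per bouton — the exact clipped sphere-box
volume is complex, and the MC error is controllable).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: neuropil background texture, vasculature
shadows, bouton shape irregularity and intensity heterogeneity beyond a
Gaussian amplitude spread, spatially varying PSFs, and tissue-shrinkage
effects on absolute sizes. The generator validates the *algorithmic*
properties (detection, merging, corrections, scaling laws); it cannot
validate staining or optics.

# Density mapping

`density_map()` slides a 1000 µm³ volume element (10 µm cube) on a regular
grid across the bounding box of a binary region mask, counts centers per
element and divides by the element volume overlapping the mask, scaled to
#/1000 µm³. The grid step defaults to 1 µm — a running average; with step
equal to the element side the elements tile the box and densities × volume
recover center counts exactly (a test invariant). Elements with less than
50% mask overlap are flagged invalid rather than reported as spuriously
low densities — precisely the artifact overlap normalisation exists to
avoid at the region boundary. `heterogeneity_summary()` reports the CV
across valid elements next to the Poisson floor `1/sqrt(mean count)`, so
genuine spatial heterogeneity is distinguishable from counting noise.

# Problem sizes used in the tests

The suite runs entirely on synthetic data, sized so the whole run stays
fast while every claim is still exercised end-to-end: detection fidelity
uses 14 µm boxes with ~15 boutons at minimum separation 2.5 µm, rendered at
0.4 × 0.34 × 0.34 µm, deconvolved 100 iterations and resampled to 0.1 µm;
likelihood monotonicity uses a 64³ phantom; boundary-model recovery uses
fields of ~3 500–5 500 boutons in 50–60 µm boxes (20 fixed-seed replicates
in the tests, 100 in the acceptance script, where counts are averaged
before fitting). The resolution check uses two 0.2 µm boutons 1.2 µm apart
under a PSF with axial/lateral sigma ratio 3.3/0.86 ≈ 3.84 at high photon
count (10⁵ per unit intensity), with regional maxima counted after
one-voxel smoothing; the pair yields one maximum before and two after
deconvolution.

# Known limitations

* The RL implementation claims no bit-compatibility with commercial
  deconvolution software; it is the standard ML algorithm with the stated
  edge handling.
* `r_leak` and `r_mg` are treated as known constants in the corrections;
  uncertainty in them propagates linearly into corrected counts and is not
  tracked.
* The boundary-effect model assumes cubic (or box) ROIs and spherical
  boutons; strongly anisotropic ROIs should use `correct_boundary_box()`,
  and non-spherical objects fall outside the model.
* Segmentation is intensity-threshold based; it requires unsaturated
  images with enough contrast to separate neighbours at *some* threshold.
  Watershed or learned segmentation is out of scope.
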