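---
title: "Methods: reading tensile stress off cell-separation images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reading tensile stress off cell-separation images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapstress)
```

## The measurement problem

In adhesion-defective plant epidermis (pectin-deficient mutants such as
*qua1*), neighbouring cells pull apart wherever tissue tension exceeds
what the compromised middle lamella can hold. A gap opens along the
shared wall, **perpendicular** to the direction of maximal tensile
stress, so the population of gap orientations in an image is a readout
of the tissue's stress pattern: transverse tension produces longitudinal
cracks and vice versa. The same logic applies to cortical microtubules
(CMTs), which align **parallel** to maximal tension. `gapstress`
implements the full quantitative chain needed to exploit these readouts:

1. threshold segmentation of separations and per-region orientation
   (`segment_separations()`, `measure_regions()`, `summarize_gaps()`);
2. axial circular statistics for populations of orientations
   (`axial_summary()`, `rao_spacing_test()`, `polar_histogram()`);
3. nematic-tensor quantification of fibrillar textures and the
   ablation-response score (`nematic_tensor_roi()`, `measure_cells()`,
   `acute_angle_to_ablation()`, `ablation_response_summary()`);
4. AFM apparent stiffness and thin-shell wall tension
   (`apparent_stiffness()`, `wall_tension()`);
5. synthetic generators with exact ground truth for every stage
   (`generate_tissue_image()`, `generate_fibril_scene()`,
   `generate_ablation_scene()`, `generate_force_curve()`).

## Gap segmentation and orientation

Separations appear in one of two intensity regimes. Open gaps (typical
of cotyledons) are *darker* than the stained walls around them; incipient
separations (stems, light-grown hypocotyls) fill with stain and appear
as *bright stripes*. `segment_separations()` therefore takes an explicit
`polarity` and selects pixels strictly below (dark) or above (bright) a
threshold. The threshold is a required argument: contrast varies image
to image, and silent automatic thresholding is exactly the kind of
decision that should stay visible. `suggest_threshold()` (Otsu) is a
documented starting point, never a default.

Selected pixels are grouped into **8-connected** components. The choice
matters for crack-like shapes, which often continue through diagonal
pixel contacts; 4-connectivity would fragment them. Components smaller
than `min_area` (default 5 µm²) are discarded — a speckle filter sized
to single-pixel staining noise at typical confocal scales, exposed as
configuration.

Each region's orientation θ_G is the axial angle of the leading
eigenvector of its pixel-coordinate covariance (a PCA of the pixel
cloud), and its anisotropy is the normalized eigenvalue difference
(λ₁−λ₂)/(λ₁+λ₂) ∈ [0, 1]. This bounded form matches the nematic-order
convention used for the CMT tensor, so gap and fibril anisotropies are
comparable. Single-pixel and moment-isotropic regions (λ₁ = λ₂, e.g. a
perfect square) have no defined orientation: they are flagged
`degenerate`, kept in area totals, and excluded from orientation
statistics rather than assigned an arbitrary angle.

Angles are measured counter-clockwise from the image horizontal in
[0, 180). The pipeline's `organ_axis` setting (default 90°, organ
vertical in the frame) rotates reported angles so that 90° always means
"along the organ axis"; this reproduces the convention in which a mean
gap angle of ~90° relative to the transverse axis signals longitudinal
cracking.

## Axial circular statistics

Orientations are axial: θ and θ+180° are the same object. All circular
machinery therefore runs on doubled angles. `axial_summary()` computes
the weighted resultant vector of 2θ; R is its length (1 = perfectly
clustered, ≈0 = no preferred orientation), the mean is the halved
argument, and the circular SD is √(−2 ln R)/2 in degrees — the standard
circular SD computed on the doubled circle and halved. The SD formula is
a documented package choice (several conventions exist); printed
"mean ± SD" values are interpretable under it. When R = 0 the mean is
undefined and reported as `NA` with infinite SD, not an error, because
antipodal configurations (e.g. equal mass at 0° and 90°) are legitimate
data.

Weighting: CMT orientation populations are weighted by per-cell
anisotropy by default (well-ordered arrays carry more orientation
information), gap populations are unweighted by default; both are
arguments, not constants.

`rao_spacing_test()` tests uniformity via Rao's spacing statistic
U = ½ Σ|Tᵢ − 360/n| on the sorted doubled angles (wrap-around spacing
included). P-values come from a seeded Monte-Carlo null (default 10⁴
replicates) rather than interpolated tables, so they are reproducible at
any n; the null is drawn through the Dirichlet representation of uniform
circular spacings (normalized exponentials), which needs no per-replicate
sorting. `rao_null_distribution()` lets batch callers draw the null once
per sample size. Ties in the data are allowed.

For linear (non-circular) quantities the package implements the
normality-gated two-sample tree used throughout this literature:
Shapiro-Wilk on both samples; any non-normal → Wilcoxon rank-sum; both
normal → Bartlett, then Student's (equal variances) or Welch's t-test.
The branch actually taken is recorded in the result (`branch_trace`), so
a reported p-value is never detached from the decision path. Constant
samples, for which Shapiro is undefined, fall to the Wilcoxon branch
with a warning.

A note on the mean-orientation oracle used in the tests: the
doubled-angle resultant mean minimizes the weighted circular squared
(chord) distance on the doubled circle. The test suite checks the
closed-form mean against an independent 0.01° grid search of that loss;
an arc-length squared loss would define a different (Fréchet) mean that
diverges from the resultant mean for dispersed samples.

## Fibril orientation: the nematic tensor

Local fibril direction is orthogonal to the local intensity gradient.
With per-pixel central-difference gradients g = (gx, gy) (edge
replication at borders), each pixel contributes the 2×2 tensor
(gy², −gx·gy; −gx·gy, gx²) — the outer product of the direction
orthogonal to g, weighted by |g|², so strong edges dominate and flat
regions contribute nothing. The tensor is averaged over the ROI and
trace-normalized; θ_M is the axial angle of the leading eigenvector and
the anisotropy λ₁−λ₂ ∈ [0, 1]. Normalizing ROI intensities first makes
the result invariant to affine intensity rescaling. The gradient
operator is the package's own fixed choice; tests assert tolerance-based
agreement (±2°) with analytic gratings rather than byte-identity with
any particular macro implementation.

ROIs are taken as given (here they come from the generators, in real use
from any cell segmentation). Erosion of segmented masks to avoid
wall-signal contamination is deliberately left upstream of
`nematic_tensor_roi()` — with exact synthetic masks it would only
discard signal, and segmentation tools already provide morphological
erosion where needed.

For ablations, the score per cell is the acute axial difference
(∈ [0, 90°]) between θ_M and the radial direction from the ablation
center to the cell centroid; 90° means circumferential alignment, the
signature of stress-driven reorientation around a wound. Reorientation
of a population shows up as a mean shift toward 90° and **negative**
skewness (mass piled at high angles). Skewness is Fisher-Pearson
g₁ = m₃/m₂^{3/2}; its significance against a normal distribution uses
D'Agostino's (1970) normalizing transformation, implemented in the
package and verified against an independent implementation on frozen
samples.

## Mechanics

`apparent_stiffness()` fits an ordinary least-squares line to the
deep-indentation part of a force curve — the points whose force lies in
a window of (by default) 75–99% of the maximal force, where the
response is turgor-dominated and nearly linear. The fit uses the raw
approach segment as recorded; 1 µN/µm = 1 N/m, so the slope is the
stiffness without conversion. The result records window occupancy and
r², and fitting fails loudly when fewer than 3 points fall in the
window. A uniform Z offset (contact-point shift) changes only the
intercept, a property the tests enforce.

`wall_tension()` is the spherical thin-shell relation σ = P·r/(2t) with
turgor P (MPa), radius r (µm) taken as the inverse of the surface mean
curvature (`radius_from_curvature()`), and wall thickness t defaulting
to 0.2 µm (200 nm), a standard value for the outer periclinal wall.
Since t is held constant, σ varies only through pressure and geometry.
The iterative deduction of P itself from force curves belongs to the
AFM-modelling literature and is out of scope: P is an input here.

## What the generators emulate — and what they do not

`generate_tissue_image()` builds a cell mosaic by seeded-region
tessellation: Poisson-disk cell centers (dart throwing with a relaxing
minimum distance), pixels assigned to the nearest center, walls rendered
where the two nearest-center distances nearly tie. Separations are
placed on cell-cell interfaces: a target orientation is drawn from the
axial von Mises law (2θ ~ VM(2μ, κ), the standard axial construction,
sampled by the Best-Fisher algorithm), the free interface with the
closest axial angle (perpendicular to the line joining the two cell
centers) is selected, and an elongated patch is painted along it —
below-background (0.02) for open dark gaps, a thin saturated band (1.0)
for bright stripes. The intensity model (background 0.2, walls 0.6) is
arbitrary but fixed for reproducibility. The default field is
1024×1024 px at 0.3638 µm/px ≈ 138654 µm², matching a typical confocal
field at this magnification. Every painted patch is recorded in the
ground-truth table with its exact pixel area and orientation, and
generation fails explicitly (never truncates silently) when the
requested number or area of gaps cannot be placed without overlap.

The generators emulate the *geometry and intensity contrast* that the
analysis depends on. They do not attempt pavement-cell lobe
morphogenesis, realistic optics (PSF, depth attenuation), 3D stacks, or
temporal gap growth. Passing the recovery tests therefore shows the
measurement chain is correct and calibrated on images with the stated
contrast structure — not that segmentation thresholds chosen for real
micrographs are optimal; those remain per-image decisions.

`generate_ablation_scene()` interpolates between no response
(orientations uniform, acute angle uniform on [0, 90], mean 45°,
SD 90/√12 ≈ 26°) and a full circumferential response via a power-law
shrink of the jitter, 90·sign(u)·|u|^{1/(1−response)}. A linear shrink
would keep the acute-angle distribution uniform (merely narrower) at
every response level and could not produce the negative skew that
characterizes real reorientation; the power-law form piles orientations
smoothly toward circumferential while preserving both endpoints.

`generate_force_curve()` produces linear, convex power-law, and
noisy-linear curves; the linear slope is recovered exactly, and the
power-law case exercises the window-dependence of the fit (deepening
the window on a convex curve raises the fitted slope).

## Problem sizes and numerical choices

Tests and examples run the tissue generator both at a quick 240×240 px
setting and at the full 372.4 µm field at half resolution (512 px,
0.7276 µm/px), which keeps the whole suite under a couple of minutes on
one CPU while preserving ≥30 gaps per field for orientation-recovery
checks, and the ablation null at n = 10⁴–2·10⁴ cells. Monte-Carlo
uniformity nulls use 10⁴ replicates by default (p-value resolution
~10⁻⁴ with an add-one estimator that never returns exactly zero). All
generator randomness flows through a single seed gate that restores the
caller's RNG state, so the generators are deterministic (bit-identical
output per seed) and side-effect-free. Degenerate inputs fail loudly
and early: thresholds outside the intensity range, infeasible gap
requests, empty windows, non-positive curvatures and zero wall
thickness all raise errors naming the offending quantity.

## Known limitations

* Gap orientation is meaningful only while separations are discrete;
  once cracks merge into networks (heavily affected tissue) the
  per-region PCA mixes branches, which mirrors the practical limit of
  the approach on real material.
* The thin-shell σ = Pr/2t assumes a spherical cap of constant wall
  thickness; strongly serrated pavement cells violate sphericity, and
  reported tensions inherit that approximation.
* The Rao Monte-Carlo p-value is exact only up to simulation error;
  with the default 10⁴ replicates the standard error near p = 0.05 is
  about 0.002.
* The synthetic mosaics use convex-ish cells; orientation statistics on
  real lobed pavement cells are unaffected (they operate on gaps, not
  cells), but wall-length-dependent quantities would not transfer.
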