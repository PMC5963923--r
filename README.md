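# gapstress

Inferring epidermal tensile-stress patterns from cell-separation images.

## The problem

In plants, the epidermis is load-bearing: turgor in the inner tissues
puts the outer cell layer under tension. When cell-cell adhesion is
compromised (pectin-deficient mutants such as *qua1*), neighbouring
epidermal cells pull apart wherever that tension exceeds what the
weakened middle lamella can hold, and a gap opens along the shared wall
**perpendicular** to the direction of maximal tensile stress. The
orientation pattern of these gaps — and of the cortical microtubule
(CMT) arrays, which align **parallel** to maximal tension — is therefore
a quantitative readout of the tissue's stress field.

`gapstress` is for researchers who want to turn such images into
numbers: it implements gap segmentation and per-region orientation
analysis, the axial circular statistics needed for populations of
orientations, nematic-tensor quantification of fibrillar textures with
ablation-response scoring, apparent-stiffness extraction from AFM force
curves with the thin-shell wall-tension relation, and synthetic-data
generators with exact ground truth so every stage can be validated
without any microscope.

## The quantities at its core

* **Gap orientation θ_G** — axial angle of the leading eigenvector of a
  segmented region's pixel-coordinate covariance; anisotropy
  (λ₁−λ₂)/(λ₁+λ₂).
* **Axial statistics** — for orientations θ ≡ θ+180°, angles are doubled
  onto the circle; the resultant vector length R ∈ [0,1] measures
  clustering, the circular mean is the halved resultant argument, the
  circular SD is √(−2 ln R)/2, and uniformity is tested with Rao's
  spacing statistic U = ½ Σ|Tᵢ − 360/n| against a seeded Monte-Carlo
  null.
* **Fibril orientation θ_M** — axial angle of the leading eigenvector of
  the trace-normalized mean nematic tensor of image gradients,
  per cell ROI; anisotropy λ₁−λ₂ ∈ [0,1].
* **Ablation response** — acute angle ∈ [0°, 90°] between θ_M and the
  radial direction from the ablation site (90° = circumferential);
  reorientation appears as a mean shift toward 90° and negative
  Fisher-Pearson skewness (D'Agostino significance test).
* **Mechanics** — apparent stiffness k: OLS slope of F vs Z restricted
  to 75–99% of maximal force (1 µN/µm = 1 N/m); wall tension
  σ = P·r/(2t) for a spherical thin shell with r = 1/(mean curvature)
  and t = 0.2 µm by default.

## Worked example

Generate a stem-like synthetic field (372.4 µm, ~138654 µm², gaps
concentrated around 90°, i.e. longitudinal cracks from transverse
tension), then run the measurement chain:

```r
library(gapstress)

spec <- tissue_spec(
  n_cells = 120, field_size = 372.4, scale = 0.7276,
  gap_polarity = "dark_gap", gap_area_fraction = 0.05, n_gaps = 40,
  orientation_mean = 90, orientation_concentration = 20, seed = 61
)
scene <- generate_tissue_image(spec)

labels  <- segment_separations(scene$image, threshold = 0.1,
                               polarity = "dark_gap", min_area = 2)
regions <- measure_regions(labels)
summary <- summarize_gaps(regions, field_area = 138654,
                          weight_mode = "anisotropy")
summary
#> Cell-separation summary: 40 region(s), 6936 um^2 of 138654 um^2 (5.00%)
#>   orientation sample: n = 40 (anisotropy-weighted)

axial_summary(summary$orientations)
#> Axial circular summary (n = 40, weighted)
#>   mean 89.3 deg +- 12.4 deg,  R = 0.911

rao_spacing_test(summary$orientations, mc_reps = 10000, seed = 62)
#> Rao's spacing test (axial): U = 271.71 deg, n = 40, p = 9.999e-05 (monte_carlo, 10000 reps)
```

All 40 generated separations are recovered; their anisotropy-weighted
circular mean (89.3°) sits within a degree of the generating μ = 90°,
the high resultant length (R = 0.91) says the orientations are strongly
clustered, and Rao's test rejects uniformity — the signature of an
anisotropic (here transverse) tensile-stress pattern. An isotropic
field (κ = 0) instead gives R near 0 and a non-significant test.

Mechanics, on a synthetic noisy force curve and a measured curvature:

```r
cv <- generate_force_curve("linear_plus_noise", true_slope = 40,
                           noise_sd = 0.6, seed = 3)
apparent_stiffness(cv)
#> Apparent stiffness k = 37.57 N/m (window 0.75-0.99 of F_max, 49 points, r^2 = 0.9771)

wall_tension(P = 1, r = radius_from_curvature(0.1), t = 0.2)
#> [1] 25
```

A command-line wrapper over the same functions is installed at
`inst/scripts/gapstress-cli.R` (subcommands `simulate`, `gaps`, `run`).

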