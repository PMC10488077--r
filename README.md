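# stromaspec

Quantitative analysis of corneal stroma tissue for wound-healing studies:
FTIR-based relative collagen and proteoglycan (PG) quantification,
depth-resolved two-dimensional correlation spectroscopy (2DCS), collagen
fibril morphometry on polarized-light images, and the accompanying group
statistics — plus seeded synthetic-data generators so the entire chain is
testable end to end without any external data.

It is written for researchers analyzing corneal (or other collagen-rich)
tissue sections who need reproducible, scriptable versions of measurements
usually spread across instrument software, ImageJ plug-ins and standalone
fiber extractors.

## What it computes

**Relative composition.** Within each band's fitting region the absorbance
is modelled as a Gaussian sum plus linear baseline,
*A*(ν) = b₀ + b₁(ν − ν̄) + Σₖ aₖ exp(−(ν − cₖ)²/2σₖ²), fit by bounded
nonlinear least squares with starting positions from Savitzky–Golay
second-derivative minima. Band areas are analytic (aσ√(2π)), and the
readouts are the ratios collagen(1338 cm⁻¹)/amide II(1550 cm⁻¹) and
PG(1064 cm⁻¹)/amide II, the PG band living inside the carbohydrate region
(984–1140 cm⁻¹).

**Depth sequencing (2DCS).** For an anterior→posterior stack of layer
spectra, dynamic spectra ỹⱼ = yⱼ − ȳ give the synchronous map
Φ(ν₁,ν₂) = (m−1)⁻¹ Σⱼ ỹⱼ(ν₁)ỹⱼ(ν₂) and the asynchronous map
Ψ(ν₁,ν₂) = (m−1)⁻¹ Σⱼₖ ỹⱼ(ν₁)Nⱼₖỹₖ(ν₂) with the Hilbert–Noda kernel
Nⱼₖ = 1/(π(k−j)). At the collagen/PG cross-peak, Noda's sign rules decide
whether the collagen signal changes before or after the PG signal along
the depth axis.

**Fibril morphometry.** A nematic-tensor anisotropy score
(λ₁−λ₂)/(λ₁+λ₂) from gradient-magnitude-weighted image orientations
(1 = perfectly parallel fibrils, 0 = isotropic), and a skeleton-based
tracer (threshold → thin → split at junctions → re-join by collinearity)
returning per-fiber length, width and straightness = chord/arc (1 =
perfectly straight).

**Statistics.** Tie-corrected Mann–Whitney U (with U reconstruction from
printed mean ranks and exact enumeration for small samples), one-way ANOVA
with Tukey–Kramer HSD, and the smallest detectable mean difference of a
two-sample t test via the noncentral-t power equation.

## Worked example

```r
library(stromaspec)

# a synthetic 25-layer depth series in which the collagen transition
# leads the PG transition by 4 layers
sim <- generate_depth_series(spectral_sim_config(lag_layers = 4,
                                                 noise_sd = 0.002,
                                                 seed = 11))

# composition of the coadded ROI spectrum
res <- fit_composition(coadd(sim$series), region_label = "Un")
res$composition
#> <composition_result> Un collagen/amideII = 0.4166, PG/amideII = 0.2829

# depth 2DCS at the collagen/PG cross-peak
maps <- correlation_maps(sim$series)
cp <- extract_cross_peak(maps)          # (1338, 1064) +/- 8 cm^-1
sequencing_call(cp)
#> <sequencing_call> direction = same, order = nu1_before_nu2
#>   (phi = 0.007928 (gate 1.51e-05), psi = 0.00193 (gate 1.93e-06))
```

The collagen/amide II ratio 0.4166 and PG/amide II ratio 0.2829 match the
generator's planted band areas (0.5·8/0.8·12 ≈ 0.417 and 0.3·10·0.905/0.8·12
≈ 0.283 after the depth profiles); Φ > 0 says collagen and PG co-vary in
the same direction with depth, and Ψ of the same sign says the collagen
change precedes the PG change — exactly the 4-layer lead that was planted.

Reconstructing a Mann–Whitney U from printed group mean ranks (4 vs 6
eyes):

```r
u_from_mean_ranks(2.75, 4, 6, mean_rank_b = 7.33)
#> [1] 1
mann_whitney(c(1, 2, 1, 2), c(3, 4, 5, 4, 3, 5))
#> <group_comparison> U = 0, Z = -2.598, p = 0.009375
#>   (mean ranks 2.50 vs 7.50; n = 4, 6)
```

A complete synthetic study (20 eyes, five region-groups, spectra + images
+ scores) and its full report:

```r
layout <- make_demo_study(seed = 42, config = demo_config())
report <- run_study(layout)
report$anova          # F tests across the five region-groups
report$twodcs         # sequencing call per region-group
report$score_stats    # Mann-Whitney table for the ordinal scores
```

A thin command-line wrapper over the same functions ships in
`inst/cli.R` (`demo` and `run` verbs).

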