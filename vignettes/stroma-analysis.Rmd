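---
title: "Quantifying corneal stroma composition and fibril architecture"
author: "stromaspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corneal stroma composition and fibril architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaspec)
```

## The analysis problem

The corneal stroma is transparent because its collagen fibrils are thin,
uniformly spaced, and stacked in orthogonal lamellae, with proteoglycans
(PGs) spacing and hydrating the fibrils. Wound healing replaces this
architecture with scar neotissue whose fibrils are shorter, wavier and less
ordered, and whose collagen/PG balance is altered. Studies of corneal
scarring therefore need three quantitative readouts from the same tissue:

1. **Relative composition** from FTIR microspectroscopy: the area of the
   collagen-specific band near 1338 cm^-1 (CH2 wagging of proline side
   chains) and of the sulfated-PG band near 1064 cm^-1 (symmetric -SO3
   stretch, inside the carbohydrate region 984-1140 cm^-1), each normalized
   by the amide II protein reference near 1550 cm^-1.
2. **Spatial co-distribution** of collagen and PGs along the
   anterior-posterior depth axis, via generalized two-dimensional
   correlation spectroscopy (2DCS) over a stack of layer spectra, with
   Noda's sign rules deciding which component changes first with depth.
3. **Fibril morphometry** on polarized-light images: per-fiber length,
   width and straightness, plus a single per-image anisotropy score.

`stromaspec` implements this chain as reusable, tested R functions,
together with synthetic-data generators that emulate the statistical
structure of such a study (two treated groups of injured eyes with scar
`Sc` and incision-adjoining `Ad` regions, plus uninjured `Un` eyes), so
that every stage can be validated against known ground truth without any
external data.

## Spectral model and band quantification

A spectrum is absorbance on a strictly monotonic wavenumber grid; the
default simulated instrument range is 4000-748 cm^-1 at a 4 cm^-1 step,
stored descending. Within each band's fitting region the model is a sum of
Gaussians plus a linear baseline,

$$A(\nu) = b_0 + b_1(\nu - \bar\nu) + \sum_k a_k
  \exp\!\left(-\frac{(\nu - c_k)^2}{2\sigma_k^2}\right),$$

fit by bounded Levenberg-Marquardt least squares (relative tolerance
1e-12, at most 500 iterations; non-convergence is flagged, never silent).
Initial peak positions come from local minima of the Savitzky-Golay second
derivative (default window 11 points, polynomial order 3): a Gaussian band
has a second-derivative minimum at its centre, which survives band overlap
far longer than the raw maximum does. Minima must reach 2% of the largest
absolute second-derivative value; ties break toward lower wavenumber; and
each defined band is guaranteed one starting candidate (inserted at the
search-window centre and flagged if none was detected). The number of
components per region is data-driven but capped at six.

Design choices that the measurement conventions leave open:

* **Baseline.** A linear baseline is fit jointly with the Gaussians inside
  each region. Joint fitting is robust and testable; a global rubber-band
  correction was considered and rejected because it couples distant
  spectral regions.
* **Band attribution windows.** Fitted components are attributed to the
  collagen and amide II bands within ±20 cm^-1 of 1338 and 1550. The PG
  band searches the whole carbohydrate region (984-1140 cm^-1) but by
  default integrates only the 1064-centred components (±20 cm^-1);
  `band_area(..., window = "search")` integrates the full region instead.
* **Areas.** Analytic, `amplitude * sigma * sqrt(2*pi)` per component,
  baseline excluded — grid-resolution independent by construction (tested:
  a 2x finer grid moves the ratios by < 0.5%).

The composition readout is the pair of ratios collagen/amide II and
PG/amide II. Ratios of areas are scale-free, so absolute absorbance
calibration, section thickness and detector gain cancel; a zero amide II
area is an error, not a zero.

## Depth 2DCS and sequencing calls

The depth stack (25 layers by default, anterior to posterior) is the
perturbation axis. Dynamic spectra subtract the depth-mean reference
(the standard convention; the choice is configurable only through the
normalization flag below):

$$\tilde y_j(\nu) = y_j(\nu) - \bar y(\nu), \qquad
\Phi(\nu_1,\nu_2) = \frac{1}{m-1}\sum_{j=1}^m \tilde y_j(\nu_1)\,
\tilde y_j(\nu_2), \qquad
\Psi(\nu_1,\nu_2) = \frac{1}{m-1}\sum_{j,k} \tilde y_j(\nu_1)\, N_{jk}\,
\tilde y_k(\nu_2),$$

with the Hilbert-Noda kernel $N_{jk} = 1/(\pi(k-j))$ off-diagonal. The
synchronous map is the sample covariance across depth (symmetric,
non-negative diagonal); the asynchronous map is antisymmetric with zero
diagonal and vanishes exactly when two profiles are proportional. Both
identities are enforced as tested invariants.

The collagen/PG cross-peak is read at the extremum of |Phi| within a
±8 cm^-1 window around (1338, 1064) — nearest-grid semantics, no
interpolation. Noda's rules then give the sequencing call: a positive
synchronous value means the two intensities change in the same direction
with depth; if the synchronous and asynchronous signs agree, the change at
nu1 (collagen) precedes the change at nu2 (PG), and if they differ it
follows it.

Two numerical gates guard sign calls near zero: `in_phase` when |Psi| is
below 1e-3 of the map's |Psi| maximum, `indeterminate` when |Phi| is below
the analogous Phi gate. The Psi gate additionally has a floor of 1e-9
times the |Phi| maximum: for perfectly in-phase data the whole asynchronous
map is zero to rounding error, so its own maximum is noise and cannot
serve as a scale. Per-layer L2 normalization (for "averaged normalized"
acquisition conventions) is available and logged but off by default; it
removes global per-layer scale factors and is covered by a dedicated test.
Scaling all layers by c > 0 scales both maps by c^2 and never changes a
call.

The phase-recovery property is tested wholesale: for planted lags of -8 to
+8 layers between the collagen and PG sigmoid depth transitions (noise
free), the call recovers the planted order for every |lag| >= 1 and returns
`in_phase` at lag 0.

## Fibril morphometry

**Anisotropy** follows the image-gradient nematic-tensor algorithm:
central-difference gradients (border excluded), per-pixel tangent
directions (gradient rotated 90 degrees) accumulated into a mean 2x2
tensor weighted by squared gradient magnitude, and the score
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ of that tensor. Magnitude
weighting makes high-contrast fibril edges dominate, so flat background
and faint noise contribute almost nothing; the score is exactly invariant
to affine intensity rescaling and invariant to rotation within
discretization error (tested at 37 degrees, tolerance 0.03). A constant
image has no defined orientation and raises an error.

**Tracing** replaces a curvelet-based fiber extractor with a defined,
fully tested procedure: Otsu segmentation (with a polarity flag for
dark-fiber images), Zhang-Suen thinning, removal of skeleton junctions
(crossing number >= 3) together with their 8-neighbourhoods, deterministic
chain walking (orthogonal steps preferred, lexicographic tie-breaks),
then re-joining of chains across junctions by collinearity: incident chain
ends pair greedily when their directions are within 45 degrees of
straight-through and the bridge direction is consistent. A second, stricter
pass (25 degrees, gap <= 40 px) handles shallow crossings, which thin to
two Y-junctions sharing a middle chain that can only be assigned to one of
the two fibers. Traced polylines are simplified with a 1.5 px
Douglas-Peucker tolerance, which removes both 8-connected staircase zigzag
and the one-pixel weave the thinning pass leaves on slanted strokes, so
pixelation does not inflate arc lengths. Per fiber: length is polyline arc length, width the path mean of
twice the Euclidean distance transform minus one, straightness the chord
over the arc. Segments shorter than 10 px (configurable) are discarded.

Because the tracer is a simplified substitute for the original curvelet
pipeline, absolute values are comparable only within this package; the
intended use — mirrored from the study design — is *between-group*
comparison, for which recovered means preserve the ground-truth rank order
(tested across generator sweeps of length, curvature and orientation
concentration) and mean length is recovered within 10% at moderate
crossing density (50 fibers of mean length 150 px on an 800 px image).

## Statistics

* `mann_whitney()` assigns midranks over the pooled sample and reports the
  smaller of the two U values, with the tie-corrected normal approximation
  $SE = \sqrt{(n_a n_b/12)\,[(N+1) - \sum(t^3-t)/(N(N-1))]}$ and no
  continuity correction — the convention under which the reconstructed
  study tables are internally consistent. Z is signed by the first group's
  U, so exchanging the groups flips its sign. Full-enumeration exact p
  values are available for pooled N <= 12; with heavy ties at small N the
  two p values agree closely in the decision-relevant tail but can drift in
  the centre of the null distribution, which is why the normal
  approximation is the reported default rather than a hybrid.
* `u_from_mean_ranks()` reconstructs U from printed mean ranks (rank sum
  minus n(n+1)/2, min convention) and refuses inputs that violate the
  rank-sum identity beyond printing precision (tolerance 0.1).
* `anova_tukey()` wraps the classical one-way ANOVA with Tukey HSD
  (Tukey-Kramer for unequal group sizes); a zero within-group variance
  with unequal means is flagged and reported as an infinite F rather than
  an error. Tests verify F and every adjusted p against textbook formulas
  evaluated independently.
* `detectable_difference()` solves the two-sided two-sample noncentral-t
  power equation for the smallest detectable mean difference; it is exactly
  scale-equivariant in the standard deviation and is cross-checked against
  both `power.t.test()` and a forward Monte-Carlo simulation. For five per
  group, sd 8 and 95% power at alpha 0.05 it returns about 20.9; published
  power-analysis software prints values in the 21-21.5 range for the same
  inputs depending on its internal algorithm, so the package documents the
  20.5-22.5 band rather than a point value.
* No multiplicity correction is applied across score parameters, matching
  the analysis convention the tables reproduce.

Histopathology-style fibrosis and inflammation grades have no published
scale range; they are modelled as ordinal 1-5 like the in-life parameters,
configurable in `score_sim_config()`.

## What the generators emulate — and what they do not

`generate_depth_series()` renders multi-band Gaussian spectra whose band
amplitudes follow depth profiles (constant, linear, or logistic sigmoid).
Sigmoids are the default for the collagen and PG bands because they give a
controllable transition layer, hence a controllable lead/lag: the planted
`lag_layers` shifts the PG transition relative to collagen (positive =
collagen leads). Real stromal gradients have no published functional form
or magnitude, so the default amplitude swing (0.7x to 1.3x across the
stack) is an order-of-magnitude choice and deliberately configurable.
The generator does not simulate FTIR optics, Mie scattering, atmospheric
bands, or detector nonlinearity — so passing tests demonstrate correctness
of the analysis chain, not robustness to those instrument artifacts.

`generate_fibril_image()` samples undirected fiber orientations from an
axial von Mises distribution (theta and theta+pi identified; kappa = 0
isotropic, kappa = Inf parallel), Gaussian lengths (clipped at 10 px),
and a sinusoidal bow whose amplitude is `curvature_amp * length`; ground
truth (polyline, arc length, chord/arc straightness, width) is recorded
*before* rasterization so tracer error is measurable. Rendering is an
anti-aliased maximum-blend stroke; background noise is Gaussian in gray
levels. Real polarized-light texture, stain variability and illumination
gradients are not simulated.

`generate_scores()` draws ordinal grades 1-5 per eye and parameter from
per-group probability vectors. One shared seeded RNG drives each
generator; a fixed seed reproduces outputs bit for bit.

## The demo study and pipeline

`make_demo_study()` builds the full design: 6 antibody-treated (ACA) and
4 vehicle-treated (Ctr) injured eyes each contributing scar (Sc) and
adjacent (Ad) regions, and 10 uninjured (Un) eyes, 25 spectral layers per
region and 3 imaged ROIs per region by default, with per-eye log-normal
jitter (4% on band amplitudes, 6% on fiber lengths, 15% on orientation
concentration, 0.5 layers on transition midpoints) so group statistics see
realistic within-group variance. Planted effects follow the qualitative
study pattern: scar regions have shorter, wavier, less aligned fibrils and
reduced collagen ratio; the treated scar additionally has a reduced PG
ratio; collagen leads the PG depth transition in Un and Sc-ACA and trails
it in Sc-Ctr, Ad-ACA and Ad-Ctr.

`run_study()` executes composition (per eye-region, on the coadded
series), depth 2DCS (per region-group, on the eye-averaged series),
morphometry (ROI means averaged per eye — the eye is the unit of
analysis), then one-way ANOVA + Tukey across the five region-groups and
Mann-Whitney comparisons of the ordinal scores. Failures are flagged per
unit and never silently dropped; given a fixed layout the report is
deterministic, and regenerating a study from the same seed writes
byte-identical files.

Problem sizes in the test-suite are desk scale by design: 112 px images
with 12 fibers and one ROI per region exercise every code path of the full
pipeline in a few seconds, and the dedicated morphometry benchmarks use
larger single images (up to 800 px). The type-I-error calibration (100
replicate null studies) runs the pipeline in `fibril_mode =
"ground_truth"`, which analyzes the generator's sampled centerlines
directly instead of rasterizing and re-tracing 3,000 images; it therefore
calibrates the aggregation and inference layers, while tracer accuracy is
covered by its own benchmarks. Ground-truth anisotropy in that mode is the
nematic order parameter of the sampled orientations,
$\sqrt{\langle\cos 2\theta\rangle^2 + \langle\sin 2\theta\rangle^2}$.

## Degenerate inputs and numerical conventions

* Wavenumber grids must be strictly monotonic; shuffled CSV rows are
  sorted descending with a warning, while ragged rows, non-numeric cells
  and duplicate wavenumbers are errors naming the offending row.
* Spectra written to CSV use 17 significant digits so a write-read
  round-trip reproduces doubles exactly.
* A flat spectrum yields no second-derivative candidates (rounding noise
  is floored), only flagged fallback candidates at band centres.
* Blank images produce an empty, flagged segmentation; constant images
  make the anisotropy undefined (error).
* All-tied score samples give U = n_a n_b / 2 and Z = 0 with a flag.
* Skeleton tracing, peak-sorting and tie-breaking are deterministic, so
  identical inputs give identical outputs with no hidden RNG use.

## Known limitations

* Absolute fibril widths depend on the distance-transform convention and
  are not comparable to curvelet-based extractors.
* Very shallow fiber crossings can still defeat the collinearity bridging;
  mean-length recovery degrades gracefully (and monotonically) with
  crossing density.
* The 2DCS sequencing call reads a single cross-peak; multi-band
  sequencing and moving-window variants are out of scope.
* The power computation assumes equal variances and normality, as the
  underlying t-test does.
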