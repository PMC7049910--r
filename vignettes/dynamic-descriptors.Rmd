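---
title: "Dynamic descriptors for DCE-MRI of cerebral small vessel disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic descriptors for DCE-MRI of cerebral small vessel disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcedyn)
```

## The problem

Subtle dysfunction of the blood-brain barrier (BBB) is thought to drive
cerebral small vessel disease (SVD).  Dynamic contrast-enhanced MRI
(DCE-MRI) probes it: after an intravenous Gadolinium bolus, serial
T1-weighted volumes show a signal increase wherever contrast
accumulates in the extracellular extravascular space.  In SVD the
leakage is small and slow, so instead of fitting a pharmacokinetic
model, `dcedyn` characterises each sampled brain region with rich
*image descriptors computed at every time point* — turning each region
into a multivariate descriptor *trajectory* — and then reduces each
trajectory to a single per-subject score that can be related to
clinical covariates.

The pipeline has five stages:

1. **Sampling** — small circular regions of interest placed on an
   anatomical template.
2. **Description** — per frame: radial power spectrum (RPS), Haralick
   features from the grey-level co-occurrence matrix (GLCM), uniform
   local binary patterns (ULBP), local configuration patterns (LCP),
   and the signal-enhancement curve (Enh).
3. **Reduction** — multivariate functional PCA (MFPCA) to one score per
   subject, region unit and descriptor.
4. **Validation** — Kruskal-Wallis tests across total-SVD-score groups
   and standardised multiple regression on age, WMH burden, sex and
   stroke lesion type.
5. **Comparators** — the scalar area under the enhancement curve
   (AUEC) and the post-peak enhancement slope, run through the same
   statistics.

Because patient data of this kind cannot be redistributed, the package
ships a digital phantom that emulates the acquisition protocol and the
cohort's covariate distributions, so every stage can be exercised,
tested and calibrated offline.

## Sampling design

Five tissues are sampled — blood vessels (BL), CSF, deep grey matter
(GMD), cortical grey matter (GMC) and white matter (WM) — with circular
non-overlapping samples of about 12 mm² in-plane, distributed over four
axial slices ("low", "low-middle", "middle-high", "high").  The
per-tier counts (e.g. 28 WM samples on the middle-high slice, 12 CSF on
the low-middle slice) are fixed by `default_sampling_plan()`.  Since
the design gives an area rather than a radius, the default radius is
`sqrt(12 / pi)` ≈ 1.954 mm.

Two departures from a manual workflow were necessary for
reproducibility:

* **Automatic placement.**  Samples are placed by seeded rejection
  sampling over the voxels carrying the tissue label on the tier's
  slice; a disc is accepted only if it lies fully inside the image,
  entirely within its tissue label, outside an optional exclusion mask
  (the stand-in for avoiding lesions, WMH and partial-volume areas),
  and does not overlap any previously placed disc on the same slice.
* **Tiers are metadata.**  Detecting the anatomical levels is out of
  scope; the tier-to-slice map is an explicit input
  (`default_tier_slices()` spreads the four tiers evenly).

A *region unit* — the granularity of all downstream analysis — is a
(tissue, tier) pair.  Units are derived from the tissues actually
present in each tier of the template; the default plan yields 13 units.

## The descriptors

### Radial power spectrum

Each frame's region is zero-embedded into an `N × N × N` cube (bounding
box centred; relative voxel geometry preserved), transformed with the
3D DFT

$$F(u,v,w) = \sum_{i,j,k} I(i,j,k)\,
  e^{-2\pi\iota (ui + vj + wk)/N},$$

and the magnitude spectrum is averaged over concentric rings of width
one: the ring of integer radius $r$ collects the frequency voxels whose
centred radius $\sqrt{u^2+v^2+w^2}$ rounds to $r$.  The continuous
spherical-shell integral that defines the ring average is not
computable on a lattice, so the discrete ring *mean* is used; it
preserves the descriptor's shape up to a ring-wise scale factor.  Note
that the magnitude $|F|$, not the squared power $|F|^2$, is averaged —
the quantity the descriptor is defined on, despite the name "power
spectrum".

Rings run to the Nyquist limit, so the descriptor has
`floor(N/2)` values: 128 at the clinical 256 reconstruction matrix, 32
at the 64-voxel cube used with the phantom grid.  (A descriptor length
of 256 would require evaluating rings beyond Nyquist, where the lattice
provides no new information; the Nyquist rule is used throughout, with
the cube side configurable.)  The DFT input volume is the *per-unit*
zero-embedded cube — a choice this package makes explicit, since discs
sample sparse locations rather than a full masked brain.

### GLCM / Haralick features

Each unit's intensities are quantised to $2^4 = 16$ grey levels by
linear binning.  The bounds are global over the unit's **entire time
series**: a per-frame min-max would renormalise away exactly the
enhancement dynamics the pipeline is designed to capture.  The
co-occurrence matrix counts 8-connected in-plane level pairs restricted
to voxels of the *same disc* (tissue purity), accumulating both
orderings so the matrix is symmetric, and is normalised by the pair
count.  Nine Haralick summaries are computed: contrast, correlation,
energy, variance, entropy, inverse difference moment (IDM), sum
average, sum entropy and sum variance.  Conventions: natural logarithm
with $0\log 0 = 0$; correlation defined as 1 when a marginal is
degenerate; the IDM denominator is the standard $1 + (a-b)^2$ (a
$1+(a+b)^2$ variant that appears in some tabulations is available
behind `idm_printed_form = TRUE`, but it is not a homogeneity measure);
sum variance is the variance of the grey-level-sum distribution around
the sum average.

### Uniform local binary patterns

For each region voxel the eight neighbours at radius 1 are compared
with the centre in the fixed order E, NE, N, NW, W, SW, S, SE; bit $p$
(weight $2^p$) is set when the neighbour is *strictly below* the
centre, so a centre of 4 with neighbours 1–8 in that order codes as
bits 1,1,1,0,0,0,0,0.  The opposite convention merely relabels the
code space bijectively; one had to be fixed, and this one is anchored
to a concrete worked example.  Codes with at most two circular 0/1
transitions ("uniform", 58 of the 256) keep their own histogram bin and
all others share one pooled bin — 59 bins, normalised to sum to one.
The u2 mapping reduces cardinality; it is *not* rotation invariant
(rotations permute uniform bins), which the rotation-invariant LCP
block below addresses.  Neighbourhoods may read image voxels just
outside the disc: discs hold only ~5–13 voxels, so interior-only
centres would leave almost nothing to encode.  Voxels whose
neighbourhood leaves the image are excluded with a warning count.

### Local configuration patterns

LCP combines rotation-invariant pattern statistics with *local
configuration coefficients* that quantify the linear dependency of a
centre on its neighbours.  Codes are pooled into the nine uniform
rotation-invariant classes (0–8 set bits).  Per class the descriptor
holds (i) the class occurrence frequency and (ii) the magnitudes of the
8-point DFT of the least-squares weights $w$ minimising
$\sum_v (c_v - x_v^\top w)^2$ over the class's voxels ($c_v$ the
centre, $x_v$ its neighbour vector); taking DFT magnitudes removes the
dependence on where the neighbour ring starts, making the block
rotation invariant.  With 9 classes × (1 + 8) values the descriptor has
exactly 81 features.  The reference construction fixes only this total,
so the block composition (occurrence + 8 magnitudes per uniform class)
is this package's explicit choice satisfying it.  Rank-deficient
normal equations — e.g. constant regions — are ridge-regularised with
$\varepsilon = 10^{-8}\,\overline{\mathrm{diag}(X^\top X)}$; empty
classes contribute zeros.

### Enhancement curve, AUEC and slope

The acquisition never defines enhancement units, so the package makes
the convention explicit: $E(t) = (\bar S_t - \bar S_0)/\bar S_0$ over
the unit's voxels (ratio by default, percent via a flag), with frame 0
the pre-contrast baseline, hence $E(0) = 0$.  AUEC is the trapezoidal
integral of $E$ over the frame times in minutes.  The slope is the OLS
slope of $E$ versus time over frames strictly after the bolus peak,
where the peak is searched only in the first third of frames: bolus
arrival is early in a ~24 min protocol, and an unrestricted argmax
would let late leakage maxima truncate the fit window.  All post-peak
frames enter the fit (the alternative — a fixed window — is unstated in
the protocol and would add a parameter with no calibration data).

## Multivariate functional PCA

Each descriptor is a $D$-element set of time curves per subject
($D = 1$ for Enh up to 128 for RPS at full resolution).  The reduction
is four-fold:

1. each element's curves are centred pointwise in $t$;
2. univariate FPCA per element: with quadrature weights $w_t$
   (trapezoidal — exact for piecewise-linear curves, the natural choice
   on a uniform frame grid), the eigenproblem of
   $W^{1/2}(X^\top X/(P-1))W^{1/2}$ gives eigenfunctions
   $\Phi_k = W^{-1/2}u_k$ with $\|\Phi_k\| = 1$ under the weighted
   inner product, and scores
   $\xi_{ik} = \sum_t w_t \Phi_k(t) X_i(t)$, the quadrature form of
   $\int \Phi_k(t)\,r_i(t)\,dt$.  The score variance of mode $k$ equals
   the $k$-th eigenvalue;
3. the per-element scores are stacked row-wise into
   $\Xi \in \mathbb{R}^{P \times \sum M^{(j)}}$ in element order;
4. eigenanalysis of $\mathrm{cov}(\Xi)$; the projection on the leading
   eigenvector is the subject's score, and the first mode's
   explained-variance fraction is reported alongside.

$M = 5$ components per element is the default: on smooth, low-rank
trajectories of the kind produced by contrast kinetics, five components
capture ≥ 99% of the univariate variance (the package treats 5 as a
fixed design constant with a config override, not as a per-dataset
selection rule, so the joint matrix has well-defined block sizes).
When a cohort is too small to support five components
(`M > min(P-1, T)`), the pipeline reduces `M` with a warning; the
strict `univariate_fpca()` interface errors instead.  Eigenvector signs
are arbitrary, so the first-mode sign is fixed by requiring a
non-negative correlation between the scores and the row sums of $\Xi$.

## Statistical validation

Scores are compared across total-SVD-score groups (0–4) with the
Kruskal-Wallis test (tie-corrected, $\chi^2$ reference with
$g - 1 = 4$ df), and regressed on age, WMH volume fraction, sex and
stroke lesion type.  The response and *all* predictors — binary ones
included — are z-scored before OLS, so each $\beta$ is a standardised
coefficient; the binary coding (female = 1, male = 0; lacunar = 1,
cortical = 0) is recorded in the output because $\beta$ signs depend on
it.  Adjusted $R^2$ uses the usual $1-(1-R^2)(n-1)/(n-p-1)$, coefficient
p-values are two-sided t-tests and the model p-value is the overall F
test.  Mirroring the analysis design, p-values are reported without
multiplicity correction; a Benjamini-Hochberg column is emitted
alongside for reference but never gates anything.  Cells that cannot be
tested (constant scores, collinear designs) are flagged in a `note`
column and skipped, so one bad cell never aborts a cohort run.

## The digital phantom

### What it emulates

* **Protocol.**  One pre-contrast volume plus 20 post-injection
  volumes at 73 s (≈24 min, 21 frames); 4 mm slices; the clinical
  256 × 192 × 42 grid at 0.9375 mm in-plane is available via
  `acquisition_geometry()`.
* **Cohort.**  Covariates are drawn from the published distribution of
  a 42-patient mild-stroke cohort: age binned in decades (39–89),
  71% male, 79% hypertensive, WMH fraction 0.07–8.73% of intracranial
  volume, total SVD score 0–4, 19/42 lacunar strokes.  WMH burden and
  SVD score are coupled through a Gaussian copula (default Spearman
  ρ = 0.6) since WMH is one of the score's constituent features.
* **Signal.**  A gamma-variate vascular input function (unit peak at
  3 min post-onset, onset at the second frame) drives each tissue's
  fractional enhancement $g\,\mathrm{VIF}(t) + \ell\int\mathrm{VIF}$;
  the leakage term emulates extravascular accumulation.  Enhancement is
  multiplicative on a per-tissue baseline, matching the T1w
  signal-increase mechanism.  Baselines, gains and leakage rates are
  order-of-magnitude choices for 1.5 T T1w imaging (vascular gain ~2,
  grey matter ~0.5–0.6, WM ~0.3, CSF ~0.05; leakage a few × 10⁻³/min)
  fixed once in `kinetics_model()`.
* **Ground-truth links.**  A subject's WMH fraction raises the WM
  leakage rate linearly (0.004/min per %WMH) and the CSF/WM texture
  heterogeneity (0.01 per %WMH), creating the associations the
  validation stage is supposed to recover.  Per-subject tissue gains
  get 15% log-normal jitter so cohorts have realistic between-subject
  variance rather than noiseless determinism.
* **Texture.**  Spatial structure is a stationary Gaussian random
  field per slice (FFT-filtered white noise, default 3 mm correlation
  length) whose relative SD is the tissue's heterogeneity — enough
  structure for GLCM/LBP/RPS to measure, fully controllable, and
  honest about being a texture *model* rather than tissue microstructure.
* **Geometry for testing.**  The default phantom grid is 64 × 64 × 8
  voxels at 1.5 mm in-plane.  The coarser spacing is deliberate: the
  12 mm² discs rasterise to ~5 voxels, so the full sampling plan
  (including 28 WM discs on one slice) remains placeable on a small
  grid while FFT cubes stay at 64³.  The label map is a concentric-ring
  brain (CSF core, GMD ring, WM annulus, GMC rim, three vessel blobs)
  scaled to the matrix so every tissue offers enough area at any grid
  size.

### What it does not emulate

No MR physics (k-space, coils, relaxometry), no motion or registration
error, no lesion geometry beyond the leakage/heterogeneity scaling, no
partial-volume mixing at tissue boundaries, and spatial texture that is
static over time.  Passing tests therefore show that the *pipeline*
recovers what was programmed into data with realistic dimensions,
noise and covariate structure — not that the descriptors are sensitive
to real SVD pathology.

## Numerical choices and degenerate inputs

* Disc rasterisation: a voxel belongs to a disc iff its centre is
  within the radius (mm, via the in-plane spacing); no partial-volume
  weighting of boundary voxels.
* Quantisation: equal-width bins with the maximum mapped to the top
  level; a constant region maps to level 0 everywhere.
* GLCM on a unit with no within-disc 8-connected pair is an error
  (degenerate matrix), caught per cell by the pipeline.
* Entropies use $0\log 0 = 0$; correlation of a degenerate marginal
  is 1.
* LCP ridge $\varepsilon = 10^{-8} \overline{\mathrm{diag}(X^\top X)}$,
  applied when the normal equations have reciprocal condition below
  $10^{-12}$.
* Ring averages of empty rings are 0; ring membership uses `round()`
  (half-up at .5 per IEEE round-half-even in R, applied identically in
  implementation and oracle).
* FPCA eigenvalues are clipped at 0 to absorb $-10^{-16}$-scale
  round-off; reconstruction with full rank is exact to ~1e-8.
* All stage randomness derives from one master seed via fixed
  per-stage offsets, so identical configs reproduce outputs
  bit-identically.

## Problem sizes used in the test-suite

The shipped tests run the complete pipeline on the 64 × 64 × 8 phantom
grid: oracle comparisons use 4³–8³ cubes (brute-force DFT), 5 × 5
patches (pair enumeration, per-voxel LBP comparison) and exhaustively
enumerated small Kruskal-Wallis datasets; FPCA calibration uses
42 subjects × 21 frames over 20 seeds; link recovery uses 20 cohorts of
100 subjects (white matter unit, enhancement descriptors); and the
type-I-error check uses 500 null regressions at n = 42.  For the null
check the response is simulated directly at the score level: with all
programmed links at zero the phantom's AUEC is a constant plus
independent measurement noise, so drawing the null response directly
is equivalent and lets 500 replicates run in seconds.

## Known limitations

* The 59-bin u2 histogram is kept at the printed size even though only
  the LCP block is truly rotation invariant.
* Frequency radii treat the cube as isotropic even when slice
  thickness differs from in-plane spacing, matching the isotropic DFT
  definition the descriptor is built on.
* Tissue labels, not anatomy, define placement; there is no automatic
  landmark detection.
* The statistics stage fits independent per-cell models; no
  longitudinal or mixed-effects structure.
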