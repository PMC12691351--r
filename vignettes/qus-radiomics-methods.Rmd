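---
title: "Methods: QUS spectral radiomics for recurrence-risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QUS spectral radiomics for recurrence-risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oncotype DX recurrence scores (ODXRS) stratify HR+/HER2−/LN− breast cancers
into recurrence-risk groups, but the assay is expensive. This package
implements, end to end and at desk scale, an imaging-based surrogate:
quantitative ultrasound (QUS) spectral parametric images of the tumor and
its 5 mm margin are summarized by radiomics features and fed to classifiers
evaluated under a nested leave-one-out protocol, dichotomizing ODXRS at a
threshold of 15 (label 1 when the score exceeds 15). Because no patient RF
data is available, a synthetic RF phantom cohort with known scattering
ground truth stands in for the clinical data; every downstream stage is
exercised and tested against that ground truth.

## The phantom simulator

A phantom is a 2-D plane of discrete sub-wavelength scatterers. Scatterer
positions are uniform with density `density_per_mm2`; amplitudes are
zero-mean Gaussian with variance equal to the local linear acoustic
concentration divided by density, so the ensemble backscatter coefficient is

    BSC(f) = 10^(AAC/10) * f^4 * exp(-2 * b_ff * k^2 * a_eff^2)

with `k = 2*pi*f/c`, the spherical Gaussian form factor with the standard
constant `b_ff = 0.827` (the source protocol does not print the constant;
it is exposed in `form_factor_config()`), effective radius `a_eff` (average
scatterer diameter ASD = `2*a_eff`), and acoustic concentration AAC in dB.
Each lateral line is synthesized in the frequency domain: scatterers form a
linearly interpolated impulse train, filtered per 0.4 mm axial slab by the
Gaussian pulse (6.5 MHz centre, 2.5 MHz spectral SD, covering the 3–8 MHz
analysis band), the `f^2` Rayleigh amplitude factor, the one-way form-factor
response, and round-trip attenuation `2*alpha*f*d` dB evaluated at the slab
centre (at most ~0.1 dB quantization at the band top, far below the
acceptance tolerances). White Gaussian noise is added at a configurable SNR
(default 30 dB relative to frame RMS).

Default acquisition geometry: 40 MHz axial sampling, 0.12 mm lateral pitch,
1540 m/s. The default scatterer density (700 per mm²) gives roughly ten
scatterers per resolution cell (lateral pitch times the effective axial
pulse extent), comfortably inside the fully-developed-speckle regime; the
Rayleigh envelope test uses thinned subsamples (~800 points) because at very
large sample sizes a Kolmogorov–Smirnov test resolves the genuine
finite-scatterer-number deviations that real tissue also exhibits.

Cohorts emulate the study composition: `n_low = 10` and `n_high = 21`
patients, elliptical cores with long axes drawn from the reported
0.7–8.9 cm range (log-normal around the reported 1.7 cm median, truncated
to the field of view), 5 mm margin rings, and ODXRS scores drawn
consistently with the class. The class effect is planted in the margin —
+3 dB acoustic concentration and stronger spatial heterogeneity (0.6 vs
0.15 modulation amplitude) for the high-risk class — mirroring the finding
that the discriminative features live in margin texture. These are
analogical study conditions for exercising the pipeline, not a claim about
patient effect sizes. Frames per patient defaults to 3 (the source protocol
never states it).

## Spectral parameter maps

A 2 mm × 2 mm window slides at 94% overlap (0.12 mm step, equal to the
radiomics resampling grid; the axial step matches the lateral step for an
isotropic map). Per window, each lateral line is Hanning-tapered, Fourier
transformed, squared, and averaged across lines in linear power. Two
corrections are applied in dB: an assumed skin layer (defaults 0.8
dB/cm/MHz over 0.2 cm, both configurable; phantoms simulate no skin, so
phantom analyses set the thickness to zero) and the tumor attenuation
estimated once per frame by the spectral difference method — per-frequency
regression of window log-power on depth, whose slope is `-2*alpha*f` — and
applied over each window's in-tumor depth.

Linear parametrization of the corrected dB spectrum over 3–8 MHz gives the
spectral slope (SS), the 0 MHz intercept (SI), and the mid-band fit,
defined at the midpoint of the analysis band (5.5 MHz): `MBF = SS*5.5 + SI`
holds exactly by construction, window by window. "Mid-band" here refers to
the analysis bandwidth rather than the transducer centre frequency; the
midpoint is configurable.

The backscatter coefficient is recovered by the reference-phantom method
(the calibration method is unstated in the source; a planar-reflector
variant is out of scope): the window spectrum is divided by the averaged
spectrum of a simulated homogeneous reference phantom with known analytic
BSC, cancelling the system transfer function. Fitting `ln BSC - 4 ln f`
against `f^2` by least squares yields ASD from the slope and AAC from the
intercept; a non-negative slope (non-physical size) yields ASD 0 with AAC
from the `f^4`-only fit, flagged. On simulated phantoms at 30 dB SNR the
median of ≥100 window estimates recovers ASD within a few percent across
40–120 µm and AAC within ~0.5 dB; attenuation recovery is within ~0.01
dB/cm/MHz of planted values in {0, 0.7}.

## Radiomics features

Per channel (MBF, SS, SI, ASD, AAC) and region (core, margin): in-mask
z-normalization scaled by 100, outlier masking at ±3 SD, resampling to the
0.12 mm grid (separable cubic-convolution interpolation — interpolating by
construction and exact on linear ramps; a prefiltered B-spline would differ
only at sub-percent level on smooth maps), fixed-bin-width discretization
(width 15 in normalized units), and a single-level undecimated Coif1
wavelet decomposition with symmetric boundary extension, so every subband
keeps the image shape and inherits the ROI mask (out-of-mask pixels are
filled with the in-mask mean before filtering to avoid boundary leakage
into the mask). The periodic core of the transform reconstructs its input
exactly.

Features per image type (original + LL/LH/HL/HH): 18 first-order, 24 GLCM
(four directions at distances 1–5, feature values averaged over all
direction-by-distance matrices — matching the cited tool's aggregation),
16 GLRLM (per-direction matrices averaged), 16 GLSZM (one 8-connected
zone matrix), 5 NGTDM and 14 GLDM (distance-1 neighborhoods, dependence
tolerance 0). Shape features (9) are computed once per patient from the
core contour: this is the only reading under which the printed total
4659 = 5×2×5×93 + 9 is achievable. Degenerate conventions follow the
standard tool behavior (constant region: GLCM correlation 1, skewness 0,
uniformity 1). Wavelet subbands are not re-discretized with a different bin
width. All 93 first-order/texture features are verified against an
independent brute-force oracle (plain double loops) to ~1e-12 relative.

Frame vectors are aggregated per patient by ROI-size weighting
(`sum(w_i v_i)/sum(w_i)`, `w` = valid pixel count), a convex combination.

## Nested leave-one-out protocol

For each of the n outer folds the left-out patient is isolated; the
development set is standardized (population SD; a development column
`{1,3}` maps to `{-1,1}`), cleaned by an isolation forest (100 random
axis-aligned trees, `ceiling(0.05*n)` most anomalous rows removed unless a
class would empty), filtered by MRMR (greedy
`relevance/(redundancy + 1e-6)` with ANOVA-F relevance and mean absolute
Pearson redundancy, k = 50), balanced — SMOTE for LDA and KNN, inverse-
frequency class weights for the SVMs and random forest (the source reports
weighting worked best for SVMs) — and searched: for every hyperparameter
grid point, sequential forward selection adds features maximizing
inner-LOOCV balanced accuracy up to k = 4; ties break toward the lower
feature index and the simpler grid point (grids are ordered by ascending
complexity). The refitted model scores the left-out sample; scores are
thresholded at 0.5 and aggregated into a single confusion matrix. SMOTE is
applied after MRMR (synthesizing in 50 rather than 4659 dimensions) and its
synthetic points participate in the inner folds; the outer test sample
never does.

SVM scores are a logistic squash of the decision margin rather than Platt
scaling: e1071's internal Platt cross-validation is unstable on ~30-sample
development sets, the 0.5 threshold coincides with the SVM class boundary
either way, and ranking metrics are invariant to the monotone map.

Grids (the source's hyperparameter table is not reproduced in the
available text; these are modest grids sized to n = 31, all exposed in
`classifier_spec()`): LDA (none), KNN k ∈ {3,5,7}, SVM C ∈
{0.1, 1, 10, 100} (+ γ ∈ {1/p, 0.01, 0.1} for RBF), RF trees ∈ {100, 300} ×
depth ∈ {2, 3, unlimited}. The complexity sweep reruns the full protocol
for 3–7 selected features and reports per-feature selection frequencies.

Metrics: the seven count-based metrics as percentages; AUROC by trapezoidal
ROC integration (equal to the tie-corrected Mann–Whitney statistic to
1e-10); AUPRC by step integration; 95% Wald intervals per proportion and a
Hanley–McNeil interval for AUROC. The published intervals for some cells
are narrower than a 1.96-SE Wald interval; intervals here are reported for
information and never used for selection.

## Univariate screening

Per MRMR-selected feature, Shapiro–Wilk normality in both groups routes to
Welch's t-test (p > 0.05 in both) or the two-sided Mann–Whitney U test
(normal approximation with tie correction; a constant group routes to
Mann–Whitney). Bonferroni adjustment over the 50 screened features gives
the 0.001 threshold. Sidedness and the Welch variant are choices the source
leaves open; both are configurable. Screening defaults to the development
set of a fold but the drivers also support whole-cohort screening.

## Problem sizes and what the tests show

The test-suite and acceptance runs use desk-scale problem sizes chosen once:
24 × 24 mm phantom frames (≥160 windows per recovery condition, two speckle
realizations), 20 random 32 × 32 images for the texture oracle, and
protocol-probing experiments on feature-level cohorts from
`simulate_feature_cohort()` (n = 31, 150 features) — 20 label permutations
under LDA with MRMR-5/SFS-1 for the leakage null (the shallowest selection
that still exercises every stage: deeper selection on null data inflates
the well-known pessimistic bias of hard-thresholded LOOCV, shifting the
null mean below 50% without indicating leakage), and a strong planted
effect (four independent margin-texture-named features shifted by 2
within-class SDs) under SVM-RBF with MRMR-12/SFS-4 for the power check. The
permutation null centres at 50% balanced accuracy only if no information
leaks from the left-out sample into any fitted statistic; a separate test
corrupts one sample and verifies its own fold's model is unchanged.

What passing does not show: the simulator has no beam diffraction,
elevational extent, phase aberration, or nonlinear propagation; margins are
geometric rings rather than infiltrative boundaries; and the planted class
effect is by construction recoverable. Results on synthetic cohorts
therefore validate the machinery — spectral estimation, feature definitions,
leakage-free cross-validation — not clinical effect sizes, and the headline
patient-cohort numbers (e.g. SVM-RBF AUROC 0.95) are reproduced only at the
level of their confusion-count arithmetic.

## Known limitations

2-D simulation plane; nearest-line scatterer assignment (no lateral beam
width, so lateral speckle correlation is absent); slab-quantized
attenuation in synthesis; attenuation estimated per frame, not per patient
(the source is silent); single-level wavelets only; no probability
calibration; no multi-class ODXRS prediction.
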