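# qusrad

Quantitative ultrasound (QUS) spectral radiomics for breast-cancer
recurrence-risk classification, as a tested desk-scale R pipeline.

The Oncotype DX Recurrence Score (ODXRS) stratifies HR+/HER2−/LN− breast
cancers by distant-recurrence risk but is costly. An imaging surrogate can be
built from raw ultrasound radiofrequency (RF) echo data: spectral analysis of
sliding windows yields five co-registered parametric maps — mid-band fit
(MBF, dB), spectral slope (SS, dB/MHz), 0 MHz intercept (SI, dB), and, via a
spherical Gaussian form-factor fit to the backscatter coefficient
`BSC(f) ∝ 10^(AAC/10) f⁴ exp(−2·b_ff·k²·a_eff²)`, the average scatterer
diameter (ASD = 2·a_eff, µm) and average acoustic concentration (AAC, dB).
Radiomics features (first-order, shape, and GLCM/GLRLM/GLSZM/NGTDM/GLDM
texture over original and Coif1 wavelet subbands — 4659 features per
patient) summarize the tumor core and its 5 mm margin, and classifiers
(LDA, KNN, linear/RBF SVM, random forest) are evaluated by nested
leave-one-out cross-validation with MRMR filtering, SMOTE or class-weight
imbalance handling, and sequential forward selection, dichotomizing ODXRS
at 15. Patient RF data is not publicly deposited, so the package ships a
synthetic RF phantom simulator with known scattering ground truth; every
stage is tested against that ground truth.

## Worked example

Simulate a homogeneous phantom with known microstructure, build its
parametric maps against a simulated reference phantom, and check recovery:

```r
library(qusrad)

acq <- rf_acquisition(depth_mm = 24, width_mm = 24, snr_db = 30)
cfg <- spectral_config(overlap_fraction = 0, skin_thickness_cm = 0)

truth <- phantom_spec(effective_radius_um = 40, aac_db = 3, seed = 5)
field <- generate_scatterer_field(truth, acq, seed = 5)
frame <- synthesize_rf_frame(field, truth, acq, seed = 5)

ref <- generate_reference_frames(acq, n_frames = 3, seed = 11)
refspec <- reference_spectrum(ref, cfg)

roi  <- roi_ellipse(c(12, 12), c(8, 8), margin_mm = 2)
maps <- build_parametric_maps(frame, roi, refspec, cfg, alpha_tumor = 0)

median(maps$channels$ASD, na.rm = TRUE)  # 80.25  (planted ASD 80 um)
median(maps$channels$AAC, na.rm = TRUE)  # 2.95   (planted AAC 3 dB)
```

The planted 80 µm scatterer diameter is recovered to within 0.3%, and the
acoustic concentration to within 0.05 dB, from 80 independent analysis
windows. The metric panel reproduces published confusion-count arithmetic
exactly; e.g. the RBF-SVM row (TP 18, FN 3, TN 10, FP 0):

```r
m <- compute_metrics(list(TP = 18, FN = 3, TN = 10, FP = 0))
round(c(m$recall, m$specificity, m$balanced_accuracy, m$npv, m$f1))
#  86 100  93  77  92
```

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end at desk scale
(one RF frame per patient on a 30 × 30 mm field of view; reduced search
grids — each script states its reductions):

```sh
Rscript analysis/01_simulate_cohort.R   # 31 phantom patients + reference
Rscript analysis/02_qus_maps.R          # five parametric maps per frame
Rscript analysis/03_features.R          # 4659 features -> results/features.csv
Rscript analysis/04_classify.R          # nested LOOCV -> results/metrics.csv
Rscript analysis/05_univariate.R        # MRMR + screening -> results/univariate_screen.csv
```

The cohort plants its class effect in the tumor margin (+3 dB acoustic
concentration, stronger spatial heterogeneity for the high-risk class), so
the expected outcome is margin-feature-driven separation; stage 04 prints
each classifier's aggregated confusion counts and AUROC, and stage 05 the
features passing the Bonferroni-adjusted 0.001 threshold.

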