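# paradiomics

Robust radiomic feature selection for photoacoustic tumour imaging.

## What this package is for

Photoacoustic (optoacoustic) tomography images tumours through the
optical absorption of haemoglobin. Radiomics — the high-throughput
extraction of histogram and texture statistics from a tumour volume of
interest (VOI) — could add far more information than the mean and median
intensities commonly reported, but radiomic features are often dominated
by acquisition and processing choices rather than by biology. This
package is for imaging scientists who want to ask, before proposing a
feature as a biomarker: *is this feature's variance driven by the tumour
type, or by the illumination wavelength, the grey-level quantisation, or
the reconstruction algorithm?*

It provides, as one tested pipeline:

- a **synthetic phantom cohort** emulating a two-arm xenograft study
  (basal vs. luminal tumour models): right-skewed vs. near-Gaussian VOI
  intensity histograms, larger and more dispersed basal volumes,
  wavelength-dependent contrast with an isobestic anchor at 800 nm, and
  two reconstruction surrogates that shift first-order statistics while
  approximately preserving skewness;
- native **3D extraction of 93 radiomic features** — 18 first-order plus
  the GLCM (24), GLDM (14), GLRLM (16), GLSZM (16) and NGTDM (5) texture
  families — with Rcpp counting kernels verified against brute-force
  oracles;
- a **balanced full-factorial sensitivity analysis**: per feature, the
  share of variance attributable to each factor as Pearson's
  η² = SS_factor / SS_total, with interactions and residual lumped into
  an *error* term so the shares sum to one; standardisation sweeps
  (fixing one factor) and five-fold coefficient-of-variation robustness;
- a **discrimination stage**: power-law volume-dependency correction,
  Kruskal–Wallis tests under Benjamini–Hochberg false-discovery control
  (q = 0.25), repeated-measures correlation pruning at |r| > 0.9 with
  single-feature classifier scores as tie-breakers, and a random forest
  whose Shapley attributions rank the surviving features.

## A worked example

```r
library(paradiomics)
cfg <- phantom_config()
specs <- make_specimens(3, 3, cfg, seed = 1)
cohort <- generate_cohort(specs, cfg, seed = 1,
                          wavelengths = c(700L, 800L, 850L),
                          grey_levels = c(8L, 64L))
wide <- extract_cohort_features(cohort$design, cohort)
long <- features_long(wide)
decomp <- eta_squared_main_effects(
  long, c("tumour_model", "wavelength_nm", "grey_levels",
          "reconstruction"))
decomp[decomp$feature %in% c("firstorder_Skewness", "firstorder_Mean",
                             "glcm_Autocorrelation"), ]
```

```
                feature tumour_model wavelength_nm grey_levels reconstruction
8       firstorder_Mean        0.543      4.17e-02       0.000       1.09e-03
15  firstorder_Skewness        0.997      3.55e-05       0.000       1.01e-04
19 glcm_Autocorrelation        0.262      1.61e-04       0.461       6.08e-08
     error degenerate
8  0.41432      FALSE
15 0.00309      FALSE
19 0.27686      FALSE
```

Each row apportions one feature's variance across the study factors.
Skewness is almost entirely driven by the tumour model (η² ≈ 1.0) and is
untouched by the grey-level setting; the mean intensity mixes model,
wavelength and unexplained variation; GLCM autocorrelation is dominated
by the grey-level quantisation — exactly the kind of confounder
sensitivity the analysis is designed to expose. The robust set at the
0.8 threshold is then:

```r
classify_robust_features(decomp)
#> [1] "firstorder_Skewness" "firstorder_Kurtosis"
```

`run_pipeline(run_config(...))` executes the whole chain — phantom,
extraction, decomposition, standardisation, fold CoV, volume correction,
Kruskal–Wallis/BH, rmcorr pruning, Shapley ranking — and persists every
intermediate table plus a JSON manifest.

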