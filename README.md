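# specmargin

Discrimination of tumor from healthy-margin tissue in FT-IR and Raman
hyperspectral maps of salivary-gland sections, for spectroscopists and
chemometricians studying label-free histopathology.

The margin around a pleomorphic adenoma is chemically heterogeneous: part
lipid-poor matrix that looks spectrally like tumor, part adipose lipid
domains with a strong ester carbonyl band at 1746 cm⁻¹. Pooled principal
component analysis of all pixels is dominated by that lipid variance, and a
classifier thresholding the PC1 score separates the classes barely better
than chance (AUC ≈ 0.6 for FT-IR). Scoring every spectrum by the
locally-baselined band integral

$$I_{1746} = \int_{1710}^{1790} \big(A(\tilde\nu) - \ell(\tilde\nu)\big)\, d\tilde\nu,$$

where $A$ is the preprocessed (smoothed, rubberband-corrected,
area-normalized) absorbance and $\ell$ the chord across the window, and
removing spectra with $I_{1746} > 0.014$ before the PCA, lifts the AUC to
≈ 0.99. The AUC is computed exactly as the Mann–Whitney statistic
$P(s_\text{margin} > s_\text{tumor}) + \tfrac12 P(\text{tie})$ on PC1
scores with a fixed margin-positive sign convention.

The package implements the whole chain — low-SNR rejection,
Savitzky–Golay smoothing, rubberband (lower convex hull) baseline
correction, cosmic-ray despiking, area normalization, lipid filtering,
PCA with group summaries, ROC/AUC and annotated loading features — plus a
calibrated synthetic generator of both tissue classes, since the original
tissue maps are not publicly deposited. See `vignettes/methods.Rmd` for
the model and its assumptions.

## Worked example

```r
library(specmargin)

ds <- sample_dataset(tissue_model("FTIR"), n_per_class = 500, seed = 7)
ds
#> <spectral_dataset> 1000 FTIR spectra, 726 points (900-3800 1/cm, ~4 1/cm spacing)
#>   classes: margin=500, tumor=500

fit_full <- specmargin(ds, lipid_filter = FALSE)
fit_full
#> PC1-score tumor-margin discrimination (FTIR)
#>   1000 spectra (margin=500, tumor=500) (unfiltered)
#>   PC1 explains 49.9% of variance; AUC = 0.517
#>   PC1 score: tumor -6.011e-05 +/- 0.0004083, margin 6.011e-05 +/- 0.002016 (SD ratio 4.94)

fit_filtered <- specmargin(ds, lipid_filter = TRUE)
fit_filtered
#> PC1-score tumor-margin discrimination (FTIR)
#>   706 spectra (margin=206, tumor=500); lipid filter retained 70.6%
#>   PC1 explains 49.2% of variance; AUC = 1.000
#>   PC1 score: tumor -0.0007058 +/- 0.0003651, margin 0.001713 +/- 0.0004463 (SD ratio 1.22)
```

Unfiltered, PC1 is the lipid axis: the margin scores are ~5× more
dispersed than the tumor's and the classes overlap (AUC 0.52). After
removing the 1746 cm⁻¹-rich spectra (29% of the dataset, all margin), the
classifier becomes essentially perfect. The annotated PC1 loading of the
full fit shows where the variance lives:

```r
head(fit_full$features[, c("wavenumber", "sign", "magnitude", "label")], 4)
#>     wavenumber     sign   magnitude                          label
#> 67        2924 positive 0.261011989 CH2 asymmetric stretch (lipid)
#> 66        2852 positive 0.242959300  CH2 symmetric stretch (lipid)
#> 170       2880 negative 0.004721601  CH3 symmetric stretch (lipid)
#> 13        1748 positive 0.192735146              ester C=O (lipid)
```

`plot(fit_full, "loading")`, `plot(fit_full, "roc")` and
`plot(fit_full, "histogram")` draw the loading plot, ROC curve and
per-class band-integral histograms; `predict(fit_filtered, newdata)`
classifies new preprocessed spectra with the Youden-optimal PC1 cutoff.
`run_full_analysis()` / `run_filtered_analysis()` wrap the same chain as
config-driven runs with JSON/CSV reports, and `read_spectra()` /
`read_jcampdx()` load real matrices instead of synthetic input.

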