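# endopH

Quantitative analysis of ratiometric endosomal pH biosensors in confocal
and STED micrographs.

Endosomes acidify from ~pH 7.4 to below 5 as they mature, but a single
fluorophore's intensity confounds pH with probe amount and vesicle size.
The SRpHi probes pair an acid-quenched fluorescent protein (EYFP, EGFP or
sepHluorin; numerator channel) with an acid-stable organic dye
(STAR400/410/512; denominator channel), so that the FP/dye intensity ratio
reports luminal pH — on individual, sub-diffraction endosomes when imaged
by STED. `endopH` implements the full measurement chain for this kind of
experiment, plus a ground-truthed synthetic image generator to validate it:

- **Photophysics** — single-site protonation (Henderson–Hasselbalch)
  brightness model: bright fraction `1 / (1 + 10^(pKa − pH))`, sensor
  ratio `R(pH) = b_fp(pH) / b_dye(pH)`, and dynamic range
  `R(pH_hi) / R(pH_lo)`. Built-in models for SRpHi1–4 (pKa 6.9 / 5.9 /
  7.1 / 6.9).
- **Synthetic data** — two-channel endosome fields with Gaussian PSF blur
  (confocal 250 nm, STED 50 nm FWHM), spectral bleed-through, Poisson +
  read noise, quantization, and exact ground truth (position, size,
  true pH).
- **Segmentation** — Otsu threshold on the acid-stable dye channel,
  8-connected components, a 5-pixel minimum object size, dual-channel
  region statistics, background ROIs, and FWHM measurement of puncta.
- **Ratiometry** — per-endosome `log10(FP/dye)`, ordinary least squares
  calibration `log10(ratio) = a·pH + b` on per-pH means, inversion back
  to pH, and empirical dynamic range `10^(a·ΔpH)`.
- **pH maps** — per-pixel ratiometric pH images with a linear LUT display,
  and per-endosome pH tables.
- **Colocalization** — centre-of-mass nearest-neighbour matching with the
  mean equivalent-disk diameter as distance threshold, and pooled
  two-tailed Student's t-tests between conditions.

## Worked example

```r
library(endopH)

s <- srphi_sensor("SRpHi1")
s
#> <SensorModel> fp: EYFP / dye: STAR410 bleed_through: 0.05

# Ideal (background-free) fold change of the FP/dye ratio from pH 7 to 5
dynamic_range(s, 7.0, 5.0)
#> [1] 44.82615

# Simulate a nigericin-equilibration standard-curve series (150 endosomes
# per pH, pH 5.0-7.0), segment it, and fit the calibration
cfg <- run_config("SRpHi1", n_per_ph = 150, seed = 42,
                  min_endosomes_per_ph = 0)
cal <- run_calibration_workflow(cfg)$curve
cal
#> <CalibrationCurve> log10(ratio) = 0.3905 * pH + -2.9071  (R^2 = 0.9691, pH 5.0-7.0)

empirical_dynamic_range(cal, 7.0, 5.0)
#> [1] 6.03867

# Image a population at pH 6.0 +/- 0.3 and recover per-endosome pH
opt <- optics_preset("confocal")
sc <- place_endosomes(150, ph_mean = 6.0, ph_sd = 0.3, seed = 7)
pair <- render_image_pair(sc, s, opt, seed = 8)
ph <- analyze_image_pair(pair, cal)
round(mean(ph$ph_ratio_of_means), 2)
#> [1] 5.89

# Centroid nearest-neighbour colocalization on a synthetic punctum pair
# with a 35% ground-truth colocalized fraction
cp <- simulate_coloc_pair(100, 0.35, seed = 9)
colocalization_fraction(segment_endosomes(cp$ch1), segment_endosomes(cp$ch2))
#> <ColocResult> 35/100 colocalized (35.0%) at threshold 7.94 px (ch1->ch2)
```

Reading the numbers: the ideal model predicts a ~45-fold ratio change over
pH 5–7, but through images with realistic background (endosomes ≈9-fold
brighter than background, no background subtraction) the measured dynamic
range compresses to ≈6-fold — which is what is observed in cells — and the
standard curve stays close to linear (R² ≈ 0.97 on per-pH means). The
recovered population mean (5.89 vs a true 6.0) reflects the linear
calibration's curvature residual, discussed in the methods vignette
(`vignettes/ratiometric-ph-imaging.Rmd`). The colocalization statistic
recovers the constructed 35% exactly.

A thin CLI over the same functions is installed at
`inst/cli/endoph.R` (subcommands: `simulate-calibration`, `simulate-coloc`,
`calibrate`, `segment`, `phmap`, `coloc`, `compare`, `fwhm`).

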