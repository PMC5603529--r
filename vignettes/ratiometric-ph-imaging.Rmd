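---
title: "Ratiometric endosomal pH imaging: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric endosomal pH imaging: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endopH)
```

## The measurement problem

Endosomes acidify as they mature, from roughly pH 7.4 in nascent vesicles to
below pH 5 in lysosomes. A single pH-sensitive fluorophore cannot report
luminal pH quantitatively from an image, because intensity also depends on
probe amount, vesicle size and optics. The SRpHi family of probes solves this
ratiometrically: an acid-quenched fluorescent protein (EYFP, EGFP or
sepHluorin) is paired with an acid-stable organic dye (STAR400/410/512), and
the FP/dye intensity ratio — not either intensity alone — encodes pH. Because
both fluorophores are compatible with stimulated-emission-depletion (STED)
nanoscopy, the ratio can be read out on individual sub-diffraction endosomes.

`endopH` implements the complete quantitative side of this experiment:

1. a parametric model of pH-dependent fluorophore brightness,
2. a ground-truthed synthetic two-channel image generator,
3. Otsu-threshold endosome segmentation with dual-channel region statistics,
4. log-linear ratio-to-pH calibration fitting and inversion,
5. per-pixel ratiometric pH maps,
6. centroid nearest-neighbour punctum colocalization, and
7. end-to-end workflows with provenance records.

## The photophysical model

The acid-sensitive protein channel follows a single-site protonation
(Henderson–Hasselbalch) response. The bright fraction at a given pH is

$$f(\mathrm{pH}) = \frac{1}{1 + 10^{\,pK_a - \mathrm{pH}}},$$

so brightness is half-maximal exactly at the pKa, and the relative brightness
between two pH values is the ratio of bright fractions (plus an optional
`acid_floor` for fluorophores with residual acid fluorescence; default 0).
With the tabulated pKa of 6.9 for EYFP this reproduces the observed residual
of about 2% at pH 5.0 relative to pH 7.0:

```{r}
eyfp <- fluorophore("EYFP", "protonation", pKa = 6.9)
100 * relative_brightness(eyfp, 5.0, 7.0)
```

The functional form is this package's modelling choice: the source
characterization reports the quenching endpoints but not a curve, and the
single-site model is both the standard description of GFP-derived
protonation quenching and consistent with the printed values.

Dye channels default to `constant` (pH-independent), reflecting the acid
stability of the STAR dyes in cells. STAR410's milder in-solution
attenuation (~37% residual at pH 5 vs 7) is available as an optional
log-linear model (`srphi_sensor("SRpHi1", star410_loglinear = TRUE)`) but is
deliberately not the default: the calibration targets are defined against
the acid-stable in-cell behaviour. Whether the dyes have any measurable pKa
of their own is not derivable from the characterization; `constant` encodes
that judgement explicitly.

The sensor-level ratio is FP over dye, so it rises with pH, and the dynamic
range over an interval is the fold change of that ratio:

```{r}
dynamic_range(srphi_sensor("SRpHi1"), 7.0, 5.0)
dynamic_range(srphi_sensor("SRpHi2"), 6.5, 4.5)
dynamic_range(srphi_sensor("SRpHi3"), 7.5, 5.5)
```

Spectral bleed-through of the protein signal into the dye detection channel
is a single scalar fraction (default 0.05, within the reported "minor,
<10%" range). It is applied by the image renderer, not by the ideal
photophysical ratio, because it is a property of the detection path.

## What the synthetic generator emulates

No imaging data are deposited for these experiments, so the generator
recreates the statistical structure the analysis assumes, with known ground
truth:

* **Scenes** — endosomes are uniform disks (a 2-D projection; no
  lumen/membrane substructure), 100–500 nm diameter by default, placed
  uniformly with a minimum separation (default 1.2 µm) by rejection
  sampling, with luminal pH drawn from a truncated normal on pH 3–9.
* **Optics** — an isotropic Gaussian PSF parameterized by FWHM
  (σ = FWHM/2.355): 250 nm at 50 nm pixels for confocal, 50 nm at 20 nm
  pixels for STED. The PSF must satisfy FWHM ≥ 2 pixels (sampling).
* **Channel amplitudes** — each endosome contributes its amplitude times
  the channel fluorophore's relative brightness at its true pH, referenced
  to pH 7.4 (the neutral baseline of newly formed vesicles).
* **Detection** — bleed-through into the dye channel, a uniform background
  (default 18 counts), Poisson photon noise, Gaussian read noise (2
  counts), and round-half-up quantization to 8 or 16 bits with saturation
  flagging. `noise = FALSE` returns the continuous ideal image, which is
  what the analytic tests exercise.

The default endosome amplitude (350 counts) was fixed so that segmented
endosomes are ≈9-fold brighter than background under default confocal
optics, matching the contrast reported for the real calibration images
(mean intensities of 161 vs 18 counts). Rendering uses 8×8 subpixel
supersampling for disk coverage and a separable, truncated (±4σ),
normalized Gaussian kernel, so that noise-free integrated signal above
background conserves the injected amplitude exactly for interior objects.

Things the generator deliberately does **not** emulate: 3-D structure,
drift, photobleaching, endosome motion, wavelength-resolved emission
spectra — and, importantly, the empirical independence of endosome size and
mean intensity. Real endosomes carry variable amounts of probe, and the
published data show essentially no size–intensity relation (R² ≈ 0.10).
Synthetic endosomes share one peak amplitude, so PSF blur makes small disks
systematically dimmer and a rendered scene shows a strong positive
size–intensity relation instead. The `size_intensity_regression` operation
is therefore validated against independent draws (where the null holds) and
the rendered-scene coupling is documented by its own test. Passing tests on
synthetic data demonstrate the correctness of the measurement chain, not
that real endosomes behave like the generator.

## Segmentation conventions

The mask is built on the acid-stable dye channel (which stays bright at all
endosomal pH; configurable), using an Otsu threshold and connected
components:

* the threshold maximizes between-class histogram variance; for
  integer-valued images whose range fits the level budget the histogram is
  exact (one bin per intensity), otherwise 256 equal-width bins span the
  observed range (bin width = range/256, the classic formulation for
  16-bit data);
* thresholding is inclusive (foreground = intensity ≥ threshold), and the
  reported threshold is the smallest foreground intensity, which makes the
  threshold shift exactly with additive intensity offsets;
* ties in the between-class variance resolve to the lowest threshold;
* components are 8-connected (the convention that keeps diagonally
  touching bright pixels together; the source does not state one);
* components smaller than `min_size = 5` pixels are discarded. The source
  states the 5-pixel rule only for colocalization; it is applied to all
  region tables here so that every analysis sees the same objects.

Region centroids are unweighted means of pixel coordinates, and the
equivalent-disk diameter is `2*sqrt(area/pi)`. FWHM measurement extracts
the brighter of the x/y profiles through a centroid, estimates local
background from the outer 20% of the profile window (6× the expected FWHM),
and interpolates the half-maximum crossings linearly; profiles that never
fall below half-maximum (overlapping or unresolved objects) fail loudly.

## Calibration: fitting, inversion and their limits

Per-endosome log10(FP/dye) ratios at each equilibrated buffer pH are
averaged, and the calibration is an ordinary least-squares line through the
per-pH means — mirroring how the published standard curves are plotted (one
averaged point per pH with SD error bars). R² is likewise computed on the
means; per-endosome scatter is kept as per-pH SDs. On the noise-free model
series over the SRpHi1 range the five-point fit gives R² ≈ 0.991:

```{r}
s <- srphi_sensor("SRpHi1")
grid <- calibration_grid("SRpHi1")
fit_calibration(grid, log10(sensor_ratio(s, grid)))
```

Two systematic effects deserve explicit statement, because they set the
accuracy limits of everything downstream:

* **Curvature residual.** The protonation response is not exactly
  log-linear over a 2-pH-unit window, so inverting the fitted line
  reproduces a pH only to within the fit residual divided by the slope —
  up to ≈0.09 pH units at the edges of the SRpHi1 range for the pure
  model. For responses that are genuinely log-linear the round trip is
  exact. Tests assert both statements; no tighter accuracy should be
  expected from a linear calibration of this model.
* **Background compression.** Following the source protocol, no background
  subtraction precedes ratioing by default. With a uniform background in
  both channels the measured ratio is pulled toward 1 where the protein
  signal is faint (acid pH), which compresses the acid end of the curve:
  under the default 9-fold-contrast conditions the full-image SRpHi1
  workflow yields R² ≈ 0.975 and an empirical dynamic range of ≈6.3-fold
  (5.0–7.0) — close to the ≈6-fold measured in cells, and far below the
  44-fold of the background-free model, for the same reason real
  measurements are. A `background_subtract` option (ROI-estimated
  background, off by default) removes the compression and restores
  R² ≥ 0.99; it is provided because the source is silent on the point.

pH estimates outside the calibration range are returned but flagged:
ratiometric variance grows rapidly outside each probe's optimal range
(SRpHi1/4: 5.0–7.0, SRpHi2: 4.5–6.5, SRpHi3: 5.5–7.5), and values there
should not be trusted quantitatively.

## pH maps

Within the mask, each pixel's pH is the calibration inversion of its
log10(FP/dye); pixels outside the mask, with zero dye signal, or saturated
in either channel carry `NA` (saturation is a display problem in the source
material; excluding such pixels from quantification is this package's
decision). The 8-bit display image maps the calibration range affinely to
0–255 — a linear LUT over pH — with background at 0. Per-endosome pH is
reported both as the mean of per-pixel pH values and as the inversion of
the ratio of channel means; the two agree exactly only for uniform-ratio
regions, and the source does not say which convention it used, so both are
emitted.

## Colocalization

The statistic is deliberately simple, matching the described analysis:
for every query-channel centroid, the Euclidean nearest partner-channel
centroid is found; objects closer than the mean equivalent-disk diameter
of the query channel's regions count as colocalized. Matching is
directional (query into partner) and many-to-one, the inequality is strict
at the threshold, and the query channel supplies the diameter average
(the source does not state which channel; the query channel is the
natural reading). Condition comparisons use a pooled-variance two-tailed
Student's t-test — "Student's" is read as the pooled test rather than
Welch's. Pixel-overlap coefficients (Pearson/Manders) are out of scope.

## Workflows, sizes and determinism

`run_calibration_workflow()` chains simulation, segmentation, ratiometry
and fitting from a serializable `run_config()`, writes the curve (JSON),
the per-endosome table (CSV), a standard-curve plot (PNG) and a provenance
record (config, seeds, package version), and warns — rather than fails —
when fewer than 150 endosomes survive per calibration pH, the working
minimum of the published standard curves. Population comparisons report
means, SDs and SEMs (captions and methods texts disagree on which to plot,
so both are emitted) plus histograms in 0.5-pH bins, left-closed and
anchored at integer pH.

Every stochastic step takes an explicit integer seed and restores the
caller's RNG state (`withr::with_seed`), so identical configurations
reproduce byte-identical outputs; the test suite hash-compares workflow
re-runs. Test and acceptance workloads use 512×512-pixel confocal fields
with 150 endosomes per calibration pH (the published per-pH n), five pH
points, and 100-punctum colocalization fields; at these sizes the complete
suite runs in under a minute on one CPU core.

## Known limitations

* The quenching model is an equilibrium two-state description; chromophore
  maturation, photobleaching and ionic-strength effects are not modelled.
* The linear calibration inherits the curvature residual discussed above;
  a sigmoidal fit would remove it but would depart from the published
  analysis and is out of scope.
* Segmentation is a global threshold plus connected components: touching
  endosomes are not split (no watershed), and dim objects near the
  threshold are lost, which slightly biases surviving-region statistics
  toward large, bright endosomes.
* The generator's size–intensity coupling (above) means conclusions about
  probe-loading statistics cannot be drawn from synthetic scenes.
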