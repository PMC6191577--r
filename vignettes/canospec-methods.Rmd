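---
title: "Methods: assessing early-season wheat biomass and nitrogen status from proximal sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing early-season wheat biomass and nitrogen status from proximal sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canospec)
```

## The problem

At early tillering (BBCH 19–30), wheat canopies are small and the view of
any nadir sensor is dominated by soil. Yet this is exactly when the first
nitrogen top-dressing is decided, so the question of whether non-destructive
proximal sensing can resolve differences in biomass and nitrogen status at
these stages matters agronomically. `canospec` implements the standard
analysis chain for that question:

1. **Green-pixel analysis** of RGB canopy photographs: convert to HSB,
   threshold the green hue band, report the green-pixel percentage as a
   canopy-cover proxy.
2. **Spectral indices**: a fixed battery of twelve two-band
   normalized-difference indices, NDSI(a, b) = (R_a − R_b)/(R_a + R_b),
   including NDVI (780, 670) and several red-edge contrasts.
3. **Contour maps**: the exhaustive R² matrix of a trait against the NDSI of
   *every* band pair, averaged over sampling dates, to locate optimized band
   combinations.
4. **Simple regression** of each predictor against the four destructive
   targets — fresh weight, dry weight (kg/ha), N concentration (% of dry
   weight) and N uptake (kg/ha, = dry weight × N% / 100) — with significance
   stars at α = 0.05 / 0.01 / 0.001.
5. **PLSR** of each trait on the full 400–1000 nm reflectance with
   seven-fold cross-validation, reporting R²cal/R²val, RMSEC/RMSEV and the
   predicted-vs-observed slopes.

Because no public plot-level dataset of this kind exists, the package ships
a synthetic canopy-scene generator that reproduces the statistical structure
the analysis assumes, so every stage is testable end to end.

## Green-pixel segmentation

A pixel is classified as plant material when hue, saturation and brightness
all fall inside closed byte-scale intervals; the default green band is hue
45–120 **on the 0–255 scale** (≈ 63.5°–169.4°), with saturation and
brightness unconstrained. This byte convention is the one used by ImageJ's
color thresholder; many other stacks put hue on 0–360° or [0, 1], so the
scale is worth stating loudly. Design choices:

* intervals are closed at both ends (integer byte semantics);
* achromatic pixels (max = min) receive hue 0 and saturation 0, so black,
  white and gray are never "plant";
* hue wraparound (lo > hi) is not supported — the green band does not wrap;
* the quantization is `round(H° × 255/360)` with R's round-half-to-even
  rule, applied identically in the generator and the segmenter, which is
  why generator images round-trip *exactly*;
* an optional rectangular crop stands in for the physical 50 × 50 cm
  sampling frame; no frame detection is attempted.

## The synthetic scene generator

The generator defines the study conditions; its defaults are not tuning
knobs.

**Traits.** Each built-in season carries per-date (min, mean, max) targets
for the four traits. Values are drawn from truncated normals matched to
those summaries (σ fixed at a quarter of the range, the untruncated mean
solved by `uniroot` so the truncated mean hits the target). A Gaussian
factor copula couples the traits within a date: fresh and dry weight at
0.97 on the latent scale, N concentration at −0.35 against dry weight
(heavier plots are more diluted). N uptake is *derived* — dry weight ×
N% / 100 — so its identity is exact on every record. The default
"2014-like" season (64 plots × 4 dates) has mean dry weight rising
450 → 2206 kg/ha while mean N concentration falls 3.2 → 2.0 %, the classic
dilution pattern; the "2016-like" season (30 sites × 2 dates, fertilized
between samplings) reverses the concentration trend. A relative measurement
jitter (3 % SD) is applied and values are clamped back into the configured
ranges; because the uptake identity and the uptake range cannot both be
enforced exactly, the sampled traits are range-enforced and uptake is
treated as derived.

**Cover.** Fractional canopy cover follows the Beer–Lambert-style closure
f = 1 − exp(−k · dry weight), with k = 4.4 × 10⁻⁴ ha/kg chosen so mean
cover sits near 18 % at the first sampling and 62 % at the last. The curve
is concave everywhere and visibly flat above 80 % cover — at 80 % the local
slope is exactly 20 % of the initial slope — reproducing the saturation
that makes high-cover canopies hard to separate by image analysis alone.

**Spectra.** Plot reflectance is linear two-endmember mixing,
R(λ) = f·R_veg(λ; N%) + (1−f)·R_soil(λ) + ε, on the 302–1148 nm / 2 nm
sensor grid. The soil endmember is a bright monotone ramp (0.10 → 0.40);
the vegetation endmember has a 550 nm green bump, a red absorption at
670 nm whose depth is affine in N concentration (0.18 at the N-poor end
down to 0.04), a red-edge inflection moving 710 → 725 nm with N, and a
0.48 NIR plateau. ε is i.i.d. Gaussian band noise (SD 0.005). This is
deliberately *not* a radiative-transfer model: no BRDF, no sun angle, no
soil moisture, no shadows. What it guarantees is the qualitative structure
the methods rely on — NDVI strictly increasing in biomass, red-edge indices
carrying an N signal distinct from cover — so passing tests demonstrate the
*machinery* is correct, not that field-data R² values are reproduced.

**Images.** A scene with target green fraction g plants exactly
round(g/100 × width × height) pixels with HSB colors drawn well inside the
green band, the rest with soil browns (hue 8–38) or, in the
`winter_stressed` style, a mix of browns and yellow-brown leaf tones
(hue 20–42) emulating cold-induced discoloration. Every color is verified
through the same byte-scale round trip the segmenter uses, so the planted
count is exact ground truth. Pixels are i.i.d. placed; the green-fraction
statistic is spatially agnostic, so no texture model is needed.

## Contour maps

For every unordered band pair in the configured window the package computes
the per-plot NDSI and its simple-regression R² against the trait, one date
at a time, then averages the per-date matrices entrywise (equal weights).
Numerical conventions:

* R² is computed by the squared-correlation identity, algebraically equal
  to 1 − SSE/SST for simple regression; the test suite cross-checks entries
  against `lm()` at 10⁻¹⁰;
* the matrix is exactly symmetric (swapping the pair flips the predictor's
  sign) and the diagonal (NDSI ≡ 0) is masked rather than reported as 0;
* pairs with a zero denominator for any plot are masked as `NA`, and masks
  propagate through date averaging; the masked count is reported;
* the default search window is 302–1048 nm; the window is a parameter
  because the full sensor span (to 1148 nm) is also legitimate;
* the best pair is the global argmax with deterministic lexicographic
  tie-breaking (smaller λ_a, then λ_b).

The inner loop is vectorized over bands: a full 424-band map on 64 plots
takes well under a second, so the exhaustive 89,676-pair search is cheap.

## Regression conventions

The pipeline default is simple linear regression everywhere; quadratic fits
for the green-pixel relationships (the curvilinear shape that appears once
cover saturates) are an explicit opt-in reported side by side, since it is
genuinely ambiguous which form a given summary table used. Slope p-values
come from the t distribution with n − 2 df (overall F for the quadratic);
stars are per-test with no multiplicity adjustment, matching the reporting
convention of agronomic index tables.

## PLSR

`mixOmics::pls` (regression mode) supplies the latent-variable
decomposition; everything around it is the package's own protocol:

* inputs are the 400–1000 nm bands, mean-centered only — autoscaling is a
  documented switch, off by default;
* plots are partitioned into seven seeded, size-balanced *random* folds
  (plots have no meaningful order here; contiguous blocks would only
  matter for spatially structured designs);
* for each candidate count 1…10, out-of-fold predictions are pooled;
  the component count minimizing pooled RMSEV is selected — the standard
  chemometric rule, consistent with the small counts (1–7) such models
  report;
* R²val is defined as 1 − PRESS/SST on the pooled out-of-fold predictions
  (it can fall below zero for a worthless model, which is informative);
  R²cal is 1 − SSE/SST on the refit; RMSEC = √(SSE/n);
* slopes are from regressing predictions on observations. For the
  calibration fit this slope *equals* R²cal (a least-squares identity), a
  useful cross-check the suite asserts at 10⁻⁸.

On the default synthetic season the pooled validated R² reaches ≈ 0.96 for
dry weight but only ≈ 0.80 for N concentration — the same qualitative
ordering field studies report (concentration is the hardest target because
its optical signal is diluted by cover), though the synthetic values are
not calibrated to any field table.

## Problem sizes and determinism

Test and demonstration runs use the scenario defaults: 64 plots × 4 dates,
128 × 128 px images, 10 candidate PLSR components, the 302–1048 nm contour
window. Every random draw is governed by one master seed (traits, spectra
and images use fixed offsets of it), so identical configuration + seed
yields a byte-identical output bundle; trait and spectra CSVs are written
at 17 significant digits so that analyzing previously simulated files
regenerates the downstream tables byte for byte.

## Known limitations

* The generator's endmembers are generic textbook shapes; no public
  reflectance magnitudes exist for plots of this kind, so absolute index
  values should not be compared against field campaigns.
* Linear mixing with additive noise cannot produce the nonlinear
  soil–vegetation interactions (multiple scattering, moisture darkening)
  real canopies show; PLSR performance on synthetic scenes is accordingly
  optimistic.
* The image model has no shadows, exposure drift or white-balance error —
  acquisition conditions the original protocols controlled physically.
* Hue quantization at the exact threshold edges can differ between software
  stacks by sub-degree amounts; fixtures are constructed away from the
  edges, and real-world thresholds should be validated per camera.
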