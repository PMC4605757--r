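---
title: "Automated segmentation of multispectral food images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated segmentation of multispectral food images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodseg)
```

## The problem

A multispectral food-imaging instrument records, for every sample placed in
its integrating sphere, a cube of reflectance images: `m x n` pixels at `W`
narrow wavelength bands (typically 18 bands between 405 and 970 nm). Only
part of each image is informative: the food sample proper. The surround
(Petri dish, packaging, byproducts) and, for meat, fat and connective
tissue must be excluded before any downstream chemometric analysis,
because every spectrum extracted from a contaminated region biases the
quality or spoilage model fitted on it. Manual segmentation is slow,
subjective and irreproducible; `foodseg` implements a fully automated,
unsupervised alternative and the evaluation statistics used to judge it.

## The procedure

The cascade implemented by `runPipeline()` has four parts.

**1. Normalization.** Each band is independently min-max scaled to [0, 1]
(`normalizeBands()`), so every band exploits the full dynamic range. Then
each pixel's W-band spectrum is centred and scaled to mean 0, sample
standard deviation 1 — the Standard Normal Variate transform (`snv()`).
For a pixel whose spectrum is `a * v + b` (gain `a` from uneven
illumination, offset `b`), SNV returns exactly the same output as for
`v`; this invariance is what removes multiplicative illumination noise,
and it is verified to 1e-9 in the test suite. Band selection and
thresholding operate on the band-normalized representation (the contrast
measure below needs nonnegative grey levels); the SNV cube is retained in
the result for spectral export.

**2. Band-pair selection.** Different samples show their
sample-vs-surround contrast at different wavelengths, so the pipeline
picks, per image, the pair of bands whose combination image best
separates the regions. The combination (`selectBandPair()`) is the signed
difference `band_i - band_j`, min-max rescaled to [0, 1]. The score is
the edge-based contrast measure (`ebcm()`): the mean over pixels of
`|I - e| / (I + e)`, where `e` is the Sobel-magnitude-weighted mean grey
level of the 3 x 3 neighbourhood. An image full of edges scores high; a
"blurry" image of a few flat plateaus scores low. The *minimum*-EBCM pair
is selected: plateaus, not detail, are what a thresholding stage wants.
Ties break to the lexicographically smaller pair, so selection is fully
deterministic.

**3. Mixture thresholding.** The winning difference image's intensity
histogram is modelled as a Gaussian mixture fitted by EM (`fitEM()`),
with the number of components (1 or 2 by default) chosen by the minimum
message length criterion (`messageLength()`, `selectModel()`):

\[ ML = \frac{N_p}{2}\sum_m \ln\frac{n\pi_m}{12} + \frac{C}{2}\ln\frac{n}{12}
   + \frac{C(N_p+1)}{2} - \log L, \qquad N_p = 2 .\]

With two components the threshold is the Bayes decision boundary — the
intensity where the two weighted component densities cross, solved in
closed form from the underlying quadratic (`bayesThreshold()`). With one
component there is no second population; instead the heavier tail
(pointed to by the sign of the sample skewness) is rejected at
`mu +/- k*sigma` (`kurtosisThreshold()`, `k = 2` by default).

**4. The two-stage cascade.** Stage 1 runs on the full image and removes
the background. Stage 2 repeats band selection and thresholding *using
only pixels inside the stage-1 mask* — both the EBCM average and the
difference-image rescaling are restricted — and removes fat and
connective tissue. Restricting stage 2 is essential: without it the
surround re-contaminates the fat/lean histogram. The final mask is the
intersection of the two stage masks, and is applied to every band with
excluded pixels set to NaN (`applyMask()`). Stage 2 is skippable for
products without a fat class, and a stage-2 failure degrades gracefully
to the stage-1 mask.

```{r example, eval = FALSE}
tt <- makePhantom(phantomPreset("meat", m = 256, seed = 1))
res <- runPipeline(tt@cube)
res
bandSummary(maskedCube(res), finalMask(res))
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cMax` | 2 | components tried by model selection: the informative area plus at most one nuisance class |
| `nBins` | 256 | histogram bins the mixture is fitted on |
| `emTol` | 1e-7 | relative log-likelihood change stopping EM |
| `maxIter` | 500 | EM iteration cap |
| `varianceFloor` | 1e-4 | variance floor, as a fraction of the data variance |
| `kurtosisK` | 2.0 | tail cutoff multiplier of the single-component path (`mu + 2*sigma` rejects about 2.3% of a Gaussian tail) |
| `foregroundRule` | `"central"` | which side of a Bayes threshold is the sample (see below) |
| `combiner` | `"difference"` | band-pair combination |
| `minSeparation` | 2.0 | bimodality guard (Ashman's D) for accepting a two-component threshold |
| `cleanupMinSize`, `cleanupMaxHole` | 0 | optional morphological cleanup, off by default |

All units are in the normalized [0, 1] intensity scale of the difference
image.

## Design choices

**Histogram EM, deterministic initialization.** The mixture is fitted on
a 256-bin weighted histogram, not on raw pixels: a 1.4-megapixel image
fits in milliseconds and the fit depends only on the histogram.
Initialization is deterministic (means at evenly spaced weighted
quantiles, equal weights, variances at the data variance) with no random
restarts, so a given cube and configuration always produce bit-identical
masks — reproducibility is the point of an automated pipeline, and the
test suite asserts it end to end.

**Signed difference, not absolute.** The band-pair combination is
`band_i - band_j` rescaled to [0, 1]; the rescale already guarantees the
nonnegative grey levels the contrast measure needs. An absolute
difference was considered and rejected: it folds regions that shift in
opposite spectral directions onto the same grey level. After per-band
min-max normalization a two-region scene (sample on surround, no fat)
places both regions at the extremes of every band, so with `|.|` every
pair difference collapses into pure noise and the method has nothing to
threshold; the signed difference keeps the two regions at opposite ends.
`"absdiff"` and `"ratio"` remain available combiners.

**Foreground-side identification.** A threshold separates two classes
but does not say which is food. The default `"central"` rule takes the
side that dominates the central 25%-area window, because samples are
centred in the dish; `"larger_component"`, `"above"` and `"below"` are
available for scenes that violate this (e.g. many small items placed
off-centre).

**Bimodality guard.** MML compares likelihood against coding cost, and
with tens of thousands of observations a slightly non-Gaussian unimodal
histogram (flat-topped, skewed) can earn a two-component fit whose
components overlap almost completely. A Bayes crossing between such
components would split a single population in half. A two-component
winner is therefore only accepted when Ashman's
`D = |mu_2 - mu_1| / sqrt((s_1^2 + s_2^2)/2)` is at least 2 — the
canonical value below which a two-Gaussian mixture has no histogram
valley; otherwise the stage falls back to the tail-rejection path.

**Tail rejection instead of a literal kurtosis rule.** For the
single-component path the implemented rule uses the *skewness* sign to
find the heavier tail and cuts at `mu + k*sigma`. (A pure Gaussian has
constant kurtosis, so kurtosis alone cannot orient a cutoff; the skew
direction can.) `k` is exposed in the configuration.

**Degenerate inputs.** Constant bands and constant-spectrum pixels map
to zeros with a flag and a warning rather than an error, so one dead
band cannot abort a batch run. Zero-edge neighbourhoods contribute zero
contrast (`e := I`, hence `c = 0`), and `c = 0` where `I + e = 0` (the
limit along `I = e`). Variances are floored at `1e-4` of the data
variance to stop component collapse on spike-shaped histograms. EM on
all-identical data returns a flagged single component.

**I/O.** Multi-page TIFF (32-bit, one page per band, wavelengths in a
JSON sidecar) covers interchange with other tools; the `tiff` writer
quantizes to 32 bits and cannot represent NaN, so the package also
defines a `.msc` archive (JSON header plus raw little-endian float64)
that round-trips cubes bitwise, including the NaN pixels of a masked
cube. Masks are single-band 8-bit PNG/TIFF, 0 = excluded, any nonzero =
included.

## The phantom generator

Real acquisitions need the instrument; the package instead generates
phantoms (`makePhantom()`) with exactly the structure the method assumes:
2-3 spectrally distinct regions (surround / sample / fat speckles), one
spectral signature per region, additive Gaussian noise
(`noiseSd = 0.02`), and a per-pixel multiplicative gain shared across
bands — the illumination structure SNV removes. The gain is drawn from a
normal centred in the gain interval and truncated at 3 sigma to its
bounds (default [0.8, 1.2]): bell-shaped illumination variation is the
plausible model for an integrating sphere, and it keeps homogeneous
regions' intensity histograms unimodal-Gaussian rather than flat-topped.
Generation is a pure function of the seed, and the truth masks partition
the image.

The presets encode the three dataset archetypes. `meat` (default
256 x 256 x 18) has a lean disk whose spectrum ramps linearly across the
bands, fat speckles whose spectrum rises in parallel up to mid-spectrum
and then folds back (so one family of pairs contrasts the whole sample
against the surround while another isolates fat against lean — the
structure the cascade expects), and a dark surround. `creme` has a single
homogeneous sample with no fat class, a narrow gain interval
([0.95, 1.05], a glossy homogeneous surface), and a surround whose
spectral slope opposes the sample's, so the two regions move in opposite
directions in every band difference. `olives` has five dark ellipses
clustered near the centre of a bright dish.

What the phantoms deliberately do *not* emulate: within-region texture
(real muscle is marbled), specular highlights, mixed boundary pixels
(point-spread blur), band-to-band noise correlation, and real instrument
spectra. Passing the phantom-recovery tests therefore shows the cascade
is correct and stable under the method's own assumptions; it does not
certify accuracy on any particular real instrument's data.

## Problem sizes and verification

The test suite verifies, among others: exact agreement (1e-12) of the
vectorized contrast measure with a literal nested-loop implementation of
its definition on random images up to 32 x 32; SNV gain invariance to
1e-9; EM log-likelihood monotonicity on every run; mixture-order
selection on 20 + 20 seeded bimodal/unimodal samples of n = 20,000 with
mean recovery within 0.01; the closed-form Bayes threshold against a
10^6-point grid search on 100 random mixtures (1e-5); end-to-end
recovery on ten seeded 256 x 256 x 18 meat phantoms (median Dice of the
final mask against the true lean region at least 0.95, fat exclusion
recall at least 0.90) and the single-component path on the crème phantom
(less than 5% of true sample pixels removed); brute-force oracles for
the evaluation statistics; and bit-identical reruns. `scripts/acceptance.R`
recomputes the headline quantities from scratch at the same sizes.

These sizes were chosen to exercise the full cascade at realistic
spatial structure while keeping a complete verification run in the order
of a few minutes; full-size 1200 x 1200 cubes run through the identical
code path (a single cascade takes on the order of a minute).

## Known limitations

- The EBCM ranking differences between candidate pairs are often small;
  which of several adequate pairs wins can change with the noise
  realization. The cascade is robust to this (any strongly separating
  pair thresholds equally well), but the *identity* of the selected pair
  is not a stable output.
- Per-band min-max normalization ties the grey scale to the extreme
  pixels of each band; a single hot pixel compresses the rest of the
  band. Real pipelines may want a percentile-based rescale; the package
  keeps strict min-max for fidelity to the normalization it implements.
- The `central` foreground rule fails when the sample does not dominate
  the image centre; use `larger_component` or an explicit side then.
- `cMax > 2` is supported by the MML machinery but untested against
  ground truth; the cascade itself only ever needs the 1-vs-2 decision.
- Runtime is dominated by scoring all `choose(W, 2)` pairs (153 for 18
  bands); restricting `candidates` in `selectBandPair()` trades
  optimality for speed.
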