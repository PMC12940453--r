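---
title: "Quantifying micrometre-scale vibration from high-speed video"
author: "vibramp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micrometre-scale vibration from high-speed video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibramp)
```

## The measurement problem

Strong diffusion-encoding gradients mechanically excite an MRI scanner and
anything coupled to it, including a phantom or patient. The resulting
surface vibrations are micrometre-scale — invisible to the eye and far below
one pixel of a high-speed camera standing outside the bore — yet they can
degrade diffusion-weighted images. `vibramp` implements a camera-based,
non-contact measurement chain for such vibrations:

1. **Eulerian video magnification (EVM)** makes sub-pixel motion in a chosen
   temporal band large enough to track;
2. **normalized cross-correlation tracking** of printed cross-shaped
   fiducial markers yields sub-pixel center positions per frame;
3. **pixel-pitch calibration and the known motion gain** of the
   amplification convert tracked excursions into physical micrometres;
4. **displacement metrics, amplitude spectra and resampling statistics**
   summarize each acquisition condition and test idle-versus-scanning
   contrasts.

Because recorded scanner videos are rarely shareable, the package ships a
first-class synthetic scene generator whose ground truth is exact. Every
stage is validated against that generator.

## Eulerian magnification model

A clip is a stack of luminance frames $I(x, y, t) \in [0, 1]$ at frame rate
$f_s$. For each location (per level of a Laplacian pyramid), the temporal
signal is filtered with an ideal DFT-mask bandpass $B$: coefficients with
bin frequency inside $[f_{lo}, f_{hi}]$ are kept, all others — including DC
— are zeroed. The output frame is

$$\tilde I = I + \alpha \, B(I),$$

reconstructed from the pyramid and clamped to $[0, 1]$. For a small
translation $\delta(t)$ of a smooth pattern whose temporal spectrum lies in
the band, first-order Taylor expansion gives an apparent translation of
$(1 + \alpha)\,\delta(t)$: the *effective motion gain* is $g = 1 + \alpha$.
The amplification factor is a description of how much of the bandpassed
signal is added back; whether displacement scales by $\alpha$ or
$1 + \alpha$ is ambiguous in common usage, so the gain is an explicit,
configurable quantity (`GainSpec`, default $g = 101$ for $\alpha = 100$)
and dividing by it reports the estimated physical motion *before*
amplification.

Design notes:

* The filter is an offline ideal bandpass over the whole clip (no
  windowing). Recorded clips are processed offline anyway, and the ideal
  filter is *exact* for tones on DFT bins, which makes closed-form tests
  possible. Its oracle in the test suite is an independently coded
  $O(N^2)$ per-bin DFT sum.
* With a uniform $\alpha$ across levels and a linear temporal filter, the
  Laplacian decomposition commutes with the filtering, so the result equals
  per-pixel amplification. The pyramid exists for the optional per-level
  schedule (`attenuateFineLevels` scales down the finest level, where
  sensor noise concentrates); it is off by default because no per-level
  schedule is specified for the reference analysis.
* Pyramid depth defaults to the deepest decomposition whose coarsest level
  keeps at least 8 px on its short side. Reconstruction is exact by
  construction (the collapse adds back exactly what the build subtracted);
  the expansion step uses normalized zero-insertion blurring so constant
  frames expand to constants including at borders.
* Clamping to $[0, 1]$ is unavoidable at $\alpha = 100$; the clamped
  fraction is reported as a warning above 1%. At the defaults below it
  stays in the low percent range.

## Tracking and calibration

The tracker matches a noise-free rendered template of each cross against a
window of $\pm$ 4 px around the previous position, by normalized
cross-correlation (illumination-invariant), and refines the integer peak
with a least-squares paraboloid over the 3×3 correlation neighborhood.

Two numerical choices matter:

* **Matched pre-smoothing.** The correlation peak of a cross template is
  nearly conical, and a 3×3 quadratic fit on a cone is biased (up to
  ~0.03 px, the classic pixel-locking effect). Frames and template are
  therefore smoothed with the same 5-tap binomial kernel before matching;
  smoothing both sides leaves the peak location unchanged while widening
  the peak, and the residual bias falls below 0.01 px.
* **Static texture offset.** A structured background under the template
  shifts the correlation peak by a small constant (up to ~0.07 px at the
  default texture amplitude). Because displacement is defined relative to
  the segment-mean position, this constant cancels exactly and does not
  affect any reported metric.

Pixel pitch is calibrated by dividing the known physical marker length by
its extent in pixels, per axis, with a first-order uncertainty from a
$\pm 0.5$ px extent-reading error; the defaults (0.49 mm/px along x,
0.46 mm/px along y, $\pm 0.01$) are the reference acquisition geometry.

Displacement in micrometres is
$\Delta(t) = (p(t) - \bar p)\, \cdot \text{mm/px} \cdot 1000 / g$,
re-centered per condition segment (segments are half-open intervals
$[t_0, t_1)$). RMS and peak-to-peak are computed on the re-centered
segment; pooled summaries take the median (midpoint convention for even
counts) and range over all marker-direction values of a condition.

## Spectra

Per axis the one-sided amplitude is $a_k = (2/N)\,|X_k|$ for
$0 < k < N/2$; the two in-plane axes are combined per bin as
$c_k = \sqrt{a_{x,k}^2 + a_{y,k}^2}$ and reported as the density
$c_k / \Delta f$ in µm/Hz with $\Delta f = f_s / N$. DC is excluded
(series are zero-mean). For even $N$ the Nyquist bin is included with
amplitude $\sqrt{2}\,|X_{N/2}|/N$, a power-preserving convention chosen so
the Parseval identity $\mathrm{rms}^2 = \sum_k a_k^2 / 2$ holds exactly for
every series, not only those without Nyquist content. The Euclidean
combination rule is isolated in one place; a sum-of-magnitudes alternative
is a one-line change. An optional Hann window (amplitude-corrected) is for
display only — the unwindowed on-bin path is the quantitative convention.

## Statistics

Displacement series are strongly autocorrelated, so both inference tools
resample contiguous blocks (default 0.1 s of frames) rather than single
frames:

* **Block bootstrap CI** — moving blocks with replacement within each
  series independently; statistic $\mathrm{rms}(a) - \mathrm{rms}(b)$ after
  re-centering; 95% percentile interval.
* **Block permutation test** — fixed contiguous blocks pooled across the
  two conditions, labels permuted preserving group sizes; statistic
  $|\mathrm{rms}(a^*) - \mathrm{rms}(b^*)|$;
  $p = (1 + \#\{\text{perm} \ge \text{obs}\}) / (n_{perm} + 1)$, so $p$ is
  never zero. On white-noise series blocks are exactly exchangeable and the
  test holds its nominal size; under strong autocorrelation it inherits the
  usual mild block-boundary leakage, which is why the block length should
  cover several correlation lengths.
* **Split-half Bland–Altman** — each segment is split at its midpoint
  (first half takes the extra frame), halves re-centered separately, and
  the percent difference of their RMS values (first minus second, relative
  to the pair mean) summarized as mean difference and limits of agreement
  $\bar d \pm 1.96\,s_d$. The reference analysis phrase "95% confidence
  intervals for the limits of agreement" is read as the LoA interval
  itself; confidence intervals *around* the LoA would need more pairs than
  a single session provides.

All resampling consumes a single seeded generator recorded in the output
JSON; identical specs reproduce identical results.

## The synthetic scene generator

`simulateClip()` renders what the analysis chain actually sees: a static
smooth background texture (blurred white noise), dark cross markers drawn
by area-weighted supersampled rasterization at continuous sub-pixel
positions, multi-tone sinusoidal motion specified in micrometres and
converted through the pixel pitch, i.i.d. Gaussian sensor noise per frame,
and exact ground-truth displacements. Area weighting (each supersample cell
contributes its covered fraction) makes the rendering exact for the
axis-aligned edges of a cross at any supersampling factor, so sub-pixel
positions are representable to machine precision and the
intensity-weighted centroid of a rendered cross matches the requested
center to well under 0.02 px.

Generator defaults, fixed once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| frame size | 128 × 128 px | desk-scale region of interest around one marker |
| frame rate | 1000 fps | resolves the 10–100 Hz band with margin |
| duration | 2 s | ≥ 80 cycles of a 40 Hz tone |
| pixel pitch | 0.49 / 0.46 mm/px | reference acquisition geometry |
| background level | 0.55 | headroom for ±0.2 amplified-noise excursions at α = 100 |
| texture amplitude | 0.02 | weak static structure, as on a matte surface |
| marker contrast | 0.45 | printed dark cross on a lighter surface |
| arm length / width | 10 / 2 mm | plausible printed-marker size; configurable |
| sensor noise SD | 0.005 | quiet machine-vision camera at high shutter rates |
| supersample | 8 | converged (exact) for axis-aligned crosses |

A 2.5 µm tone at this geometry is ≈ 0.005 px — comfortably invisible — and
amplification at α = 100 turns it into ≈ 0.5 px, which the tracker
resolves to a few percent.

What the generator deliberately does **not** model: mirror-path geometry
and mirror-induced artifacts, illumination flicker, rolling shutter,
frame-rate jitter, photorealistic surfaces, and non-sinusoidal transients
(the jump when gradients switch direction). Passing tests therefore
demonstrate the correctness of the analysis chain on its stated model, not
robustness to all artifacts of a real scanner room; the idle-condition
noise floor measured on synthetic scenes (~0.5–0.8 µm RMS through the full
pipeline at the defaults) should be re-established per site on real
footage.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script run the full chain on
128 × 128 px, 2 s, 1000 fps clips for parameter recovery; 20 seeded
idle-versus-scan pairs on 48 × 48 px, 1 s, 500 fps clips for the
discrimination study (block length 0.1 s gives 10 + 10 pooled blocks, so
the permutation floor $1/500$ sits well below the 0.01 decision level);
200 white-noise pairs for the size check; and 48 synthetic series pairs
for the split-half stability study. These sizes were chosen so the whole
validation runs on a laptop-class single core in a few minutes while every
statistical check retains clear margins.

## Known limitations

* The ideal bandpass assumes the whole clip is available; there is no
  streaming mode.
* Motion gain $g = 1 + \alpha$ is a first-order result; it degrades once
  the amplified excursion approaches the template's edge-transition scale
  (the linearity test keeps $(1+\alpha)\delta$ below a quarter of the arm
  width).
* At $\alpha = 100$ the amplified in-band sensor noise sets the detection
  floor; displacement below the static-scene control RMS should not be
  interpreted.
* Condition timing comes from the run configuration; synchronizing video
  to the pulse sequence (e.g. via audio) is out of scope.
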