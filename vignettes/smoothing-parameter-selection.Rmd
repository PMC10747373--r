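---
title: "Selecting the NLM smoothing factor from a thin/thick detector pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the NLM smoothing factor from a thin/thick detector pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scintopt)
```

## The procedure and its assumptions

`scintopt` addresses a concrete calibration question in radiographic
detector practice: given a sharp-but-noisy image from a thin scintillator
and a clean-but-blurry image of the same scene from a thick one, how much
non-local-means (NLM) smoothing should be applied to the thin image so that
it inherits the thick detector's noise behavior without giving up the thin
detector's resolution?

The answer is framed as a one-dimensional sweep. For each smoothing factor
$h$ on a grid, the thin image is denoised and two dimensionless scores are
evaluated:

* the **edge preservation index** (EPI) of the denoised image against the
  raw thin image — a normalized cross-correlation of mean-subtracted
  Laplacian fields over an edge-bearing ROI. It equals 1 when the edge
  structure is untouched and decreases as smoothing spreads edges.
* the **normalized SNR** — mean/standard deviation over a homogeneous ROI
  of the denoised image, divided by the same quantity measured on the
  thick image. Dividing by the thick detector's SNR puts the score on the
  same unit scale as the EPI: the value 1 means "as clean as the thick
  screen".

EPI is monotone decreasing and the normalized SNR monotone increasing in
$h$ (asserted as a test property on the simulated study), so the two curves
cross at most once in practice; the crossing abscissa $h^*$ is returned as
the optimum, linearly interpolated between the two bracketing grid points.
The procedure assumes (i) the two images show the same scene at the same
geometry, so the thin image can serve as the sharpness reference and the
thick image as the noise reference; (ii) the ROIs are well chosen — the EPI
ROI must contain real edge structure and the SNR ROI must be nominally
uniform; and (iii) the denoiser's response to $h$ is smooth enough that a
100-point grid resolves the crossing.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `h_min`, `h_max` | $10^{-3}$, $10^{-1}$ | normalized intensity | two decades bracket "imperceptible" to "aggressive" smoothing on a unit scale |
| `n_steps` | 100 | — | resolves the crossing to ~5% in $h$ on a log grid |
| `grid_spacing` | log | — | a two-decade range needs uniform resolution per decade; linear available |
| `patch_radius` | 1 (3×3 patch) | px | smallest centered patch that captures local texture |
| `window_radius` | 2 (5×5 window) | px | smallest window giving a meaningful neighbor population |
| `oversample` (MTF) | 4 | — | sub-pixel ESF binning; 8 available for steep edges |
| `roi_size` (NNPS) | 128 | px | on a 512×1024 frame leaves 105 half-overlapping ROIs per frame |
| `band_halfwidth` (NNPS) | 7 | rows | the customary seven lines flanking each frequency axis |

The patch/window sizes deserve a note: a "2 × 2" patch or window cannot be
centered on a pixel, so the package adopts the nearest odd-sized centered
equivalents (3×3 patch, 5×5 window) and exposes both radii as
configuration.

`h` is deliberately scale-free: images are min-max normalized to $[0, 1]$
before the patch-distance weighting and restored to their native scale
afterwards, so the same `h` value means the same relative smoothing on
8-bit, 16-bit or float inputs. One consequence worth knowing: on a pure
noise field (e.g. a flat-field frame) the dynamic range *is* the noise
excursion, so a given `h` corresponds to far weaker smoothing there than on
an image whose range is set by real contrast. Denoising flat-field stacks
at the $h^*$ selected on an edge scene therefore changes their NNPS only
marginally; the package's guarantees about the denoised NNPS are stated as
"never above the raw thin NNPS", not as a fixed reduction.

## What the simulator emulates — and what it does not

The `phantom_sim` chain renders a noiseless scene (flat field, square-wave
line-pair bands, or a tilted edge with exact sub-pixel area fractions) and
exposes it through: Gaussian PSF blur (reflective boundaries) → quantum
gain → per-pixel Poisson sampling → additive Gaussian read noise →
clipping and integer quantization. This reproduces the *statistical
structure* the optimizer relies on — Poisson-dominated noise whose power
scales with gain, blur that trades off against that noise, and a fixed
48 µm / 16-bit sensor geometry — with full determinism given a seed.

Scintillator thickness is represented operationally, not physically: the
"thin" preset uses (PSF σ 0.040 mm, gain 40) and the "thick" preset
(0.060 mm, gain 100), both with 8 counts of read noise. The thin blur value
is a deliberate calibration: at 48 µm pitch a discrete Gaussian much
sharper than σ ≈ 0.8 px transmits so much Nyquist-frequency content that
the chain's MTF never falls to 10% below the Nyquist frequency, and the
10%-MTF figure — the package's scalar resolution readout — would sit
pinned at the grid edge for the thin and lightly-denoised images alike.
σ = 0.040 mm places the thin detector's 10% point near 8 lp/mm, safely
inside the measurable band, while preserving every qualitative ordering
the presets exist to emulate (thin sharper and noisier, thick blurrier and
cleaner).

Not modeled: energy-dependent absorption, optical cross-talk, detector lag
or ghosting, structured (fixed-pattern) noise, and the heel effect. Passing
tests on the simulator therefore demonstrate the *method's* correctness —
oracle agreement, closed-form spectra, analytic MTFs, ordering properties —
not the behavior of any physical detector; on real data the flat-field
pre-processing those effects require is the user's responsibility.

## Numerical choices

* **NLM evaluation.** The accelerated path iterates over the 25 window
  offsets, computing all patch distances for one offset at once with a
  summed-area-table box filter; it is algebraically identical to the
  brute-force reference path, which is kept as the test oracle (agreement
  to $10^{-10}$). The patch distance is the unweighted mean squared
  difference over patch pixels; the self-weight is included as computed
  ($e^0$ before normalization); weighting uses the neighbor values, making
  every output a convex combination of its search window. Reflective
  padding keeps the weight normalization exact at borders. A constant
  image short-circuits to itself.
* **EPI.** The Laplacian is the four-neighbor 3×3 kernel with reflective
  boundaries, applied to the full image before ROI extraction so the ROI
  boundary carries no filtering artifacts. A zero-variance Laplacian in
  either image is a distinct, explicit error. The population (divisor N)
  standard deviation is used in the SNR so exactness tests have a fixed
  convention.
* **NNPS.** The mean frame is subtracted, differences are tiled into
  half-overlapping ROIs, and the averaged periodogram is scaled by
  $\Delta x \Delta y / (N_x N_y)$ so values carry mm² units and the
  white-noise closed form $\sigma^2 \Delta^2 / \mu^2$ holds. Subtracting
  the ensemble mean of $M$ frames leaves a known $(M-1)/M$ factor in the
  noise power; no bias correction is applied, which keeps Parseval's
  identity exact for the estimator and stays well inside the tolerance of
  every comparison at the package's 16-frame default. The DC bin and both
  zero-frequency axes are excluded from all 1-D averages.
* **MTF.** Slanted-edge, ISO-12233-style: per-row edge localization by the
  centroid of the absolute row derivative *within ±8 samples of the
  derivative peak* (a full-row centroid is dragged toward the ROI center
  by noise), a least-squares line through the row positions, projection
  onto the edge normal, ESF binning at pitch/oversample, central-difference
  LSF, Hann window centered on the LSF peak, FFT, DC normalization. Both
  the finite-difference derivative response and the bin-aperture sinc are
  divided out — without the latter the noiseless pixel-aperture oracle
  misses its 2% band near 0.8 × Nyquist at oversample 4. Empty ESF bins
  are linearly interpolated, with more than 10% empty treated as an
  unusable tilt. If the curve never reaches 0.10 before Nyquist, `f10` is
  reported as Nyquist with an explicit flag rather than extrapolated.
* **Crossing selection.** An exact zero of EPI − SNR̂ at a grid point wins
  (first such point); otherwise the first sign change is interpolated —
  in $\log_{10} h$ on the log grid, in $h$ on a linear grid. Multiple
  crossings take the first (lowest $h$), favoring sharpness. "No crossing"
  is a status, not an exception, so callers can treat an uncrossed sweep
  as data.

## Problem sizes used by the tests

The test suite runs the full study in a reduced geometry chosen to keep the
simulated conditions intact while the suite stays fast: 256 × 256 images
with a 25-step sweep for the end-to-end orderings (the crossing, curve
monotonicity, NNPS and 10%-MTF orderings), 8–16-frame flat stacks for the
spectral checks, and five seeds for the crossing-robustness property. The
acceptance script (`scripts/acceptance.R`) runs the same pipeline at the
full 512 × 1024 geometry with the 100-step grid.

## Known limitations

* The optimum is a property of the *pair* of images and the chosen ROIs;
  there is no claim that $h^*$ transfers across exposure conditions beyond
  the paired acquisition it was derived from.
* Only the smoothing factor is optimized; patch and window sizes are held
  fixed. Joint optimization over all three NLM parameters is out of scope.
* The no-reference (BRISQUE-style) quality hook delegates to an external
  backend registered at run time; the package ships no natural-scene
  statistics model of its own and raises a capability error when no
  backend is present.
* The NNPS stack assumes detrending by mean-frame subtraction only; flats
  with low-frequency structure (heel effect, off-focus shading) need
  external flat-field correction first.
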