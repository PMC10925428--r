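---
title: "Methods: allele-level DNA/RNA FISH image analysis"
author: "HTFISH package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-level DNA/RNA FISH image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HTFISH)
```

# The analysis problem

Combined DNA and RNA fluorescence in situ hybridization (FISH) in a
high-throughput 384-well format images three channels per field: DAPI
(nuclear stain), a DNA probe marking the two copies of a gene locus, and an
intronic RNA probe marking sites of nascent transcription. Because both
alleles of a gene are resolved in each nucleus, transcription can be scored
*per allele*: a DNA spot with an RNA spot nearby is an actively transcribing
allele, one without is inactive. Combined with the nuclear radial position
of each DNA spot, this supports asking whether active and inactive alleles
occupy different nuclear locations.

Two acquisition protocols exist. In the *simultaneous* protocol, DNA and RNA
probes are hybridized together and all three channels share one coordinate
frame. In the *sequential* protocol, RNA (with DAPI) is imaged first, then
DNA (with DAPI) in a second session; the stage does not return to the exact
position, so the two rounds are related by an unknown in-plane translation
that must be estimated from the shared DAPI structure before DNA and RNA
coordinates can be compared.

HTFISH implements the full analysis as composable stages, each of which can
be validated independently against a seeded synthetic-image generator that
knows its own ground truth. Images here are 2D maximum projections; no
z-resolved analysis is attempted.

# Registration of sequential rounds

For a reference image $A$ (DNA round) and moving image $B$ (RNA round), the
cross-correlation at integer displacement $(\Delta x, \Delta y)$ is

$$C(\Delta x, \Delta y) = \sum_{x,y} A(x, y)\, B(x - \Delta x, y - \Delta y),$$

summed over the overlap region, and the estimated translation is the peak
$(\Delta x_{peak}, \Delta y_{peak})$. The registered image is
$B_{reg}(x, y) = B(x - \Delta x_{peak}, y - \Delta y_{peak})$ with vacated
boundary pixels set to zero. Indexing $B$ with the *negative* displacement
inside the sum makes the peak argument exactly the vector to apply: the two
formulas are mutually consistent by construction, and
`applyShift(moving, estimateShift(ref, moving))` aligns the pair.

Numerical choices:

* **Zero-mean correlation by default.** The raw product sum of two
  non-negative images is biased toward displacements that maximize overlap
  area rather than structural agreement; subtracting each image's mean
  removes this. `correlation = "raw"` preserves the verbatim sum for
  comparison.
* **FFT with a direct-sum oracle.** The surface is computed by zero-padded
  FFT for speed, but the implementation is required (and tested) to equal
  the literal spatial-domain double sum at *every* displacement to a 1e-6
  relative tolerance — with zero padding the two are mathematically
  identical, so observed agreement is at machine precision.
* **Integer shifts only.** Sub-pixel registration is deliberately omitted:
  the residual quantization of at most one pixel (0.108 µm) is negligible
  against the 1.0 µm activity threshold downstream.
* **Bounded search, deterministic ties.** The search is limited to
  `maxShift` (default 50 px) to reject spurious far peaks; exact peak ties
  break toward the smallest $|\Delta x| + |\Delta y|$, then smallest
  $\Delta y$, then $\Delta x$.
* Constant (zero-variance) images are rejected as degenerate rather than
  returning an arbitrary peak.

# Nucleus segmentation and quality control

Nuclei are segmented from DAPI by a classical pipeline chosen to satisfy the
same output contract as learned segmenters: Gaussian smoothing (default
sd 2 px), Otsu global threshold, hole filling, and a distance-transform
watershed to split touching nuclei, followed by removal of components below
`minAreaPx` (default 500 px, ~5.8 µm² at 0.108 µm/px). Segmentation is
deterministic; an all-background image yields an empty mask, not an error.

Per-nucleus geometry is measured in physical units: area, equivalent
diameter $d = 2\sqrt{A/\pi}$, perimeter, and circularity
$c = 4\pi A / P^2$ (clipped at 1.05 to tolerate rasterization). The
perimeter uses a Cauchy–Crofton estimate from boundary intercepts along four
line directions; a naive pixel-edge count overestimates the perimeter of a
disc by a factor approaching $4/\pi$ and would push the circularity of
perfectly round nuclei far below any usable cutoff.

The segmentation-error filter removes nuclei *smaller than 10 µm with
circularity below 0.95*. Read literally this is a conjunction, and the
default (`qcLogic = "and"`) implements it as written; since the plausible
intent is that either defect alone marks a segmentation error, `"or"` is
available as a configuration switch. "Smaller than 10 microns" is
interpreted as equivalent *diameter* (microns are a length); the cutoff is
exposed as `minDiameterUm`. Border-touching nuclei are kept by default
(`dropBorder = FALSE`), as no border rule is part of the filter.

# Spot detection

FISH signals are near-diffraction-limited, so a single-scale
Laplacian-of-Gaussian detector is used: the image is convolved with a
negated, zero-sum, $\sigma^2$-normalized LoG kernel (default
$\sigma = 1.5$ px, configurable per channel), local maxima within the
minimum-separation radius (default 3 px) are thresholded, and each kept
peak is refined to sub-pixel position by a separable quadratic fit on its
3×3 neighbourhood, falling back to the integer position when the fit is not
concave or the peak touches the border.

The `"auto"` threshold is the Otsu threshold of the positive LoG response
values, floored at 6 robust (MAD-based) standard deviations of the full
response. The floor matters: on a pure-noise image Otsu simply bisects the
noise distribution and would report hundreds of spots, while the maximum of
~2.6×10⁵ correlated Gaussian response values stays below 6 robust sd with
high probability — the suite verifies at most 1 false detection per 10
blank images. Thresholding is applied after maximum selection, so raising
the threshold can only remove detections (monotonicity).

Each spot is assigned the nucleus label of the mask pixel containing its
rounded center; spots over background (label 0) are excluded from all
downstream allele analysis, implementing the rule that spots not
overlapping any nucleus are filtered out. No nearest-nucleus rescue within
a radius is attempted.

# Allele gating and classification

Per nucleus and channel, spot counts are binned "0" / "1" / "2" / "≥3".
Only QC-passing nuclei with exactly 2 DNA spots and at most 2 RNA spots are
gated into allele analysis; each gated cell contributes exactly two allele
records (a conservation law the tests assert).

For a gated cell, all pairwise 2D Euclidean distances between DNA and RNA
spots are computed in microns and each DNA spot takes its minimum over RNA
spots. A cell with no RNA spot leaves both distances undefined → both
alleles `NoTranscription`. A distance strictly below `activityThresholdUm`
(default 1.0 µm) → `Active`; otherwise `Inactive`. The strict inequality
follows the "below 1 micron" reading; the boundary case of exactly 1.0 µm
is therefore Inactive, and the threshold is configurable where the
inclusive reading is preferred. RNA spots are not exclusively matched: the
per-DNA-spot minimum permits two DNA spots to claim the same RNA spot; no
assignment problem is solved, which matches the per-spot-minimum
definition and keeps the statistic order-independent.

Expression states per nucleus follow from the allele calls: biallelic =
2 Active, monoallelic = 1, silent = 0, with fractions over gated nuclei
summing to 1.

# Radial position

For each nucleus, the Euclidean distance transform of its binary mask
(distance of every nucleus pixel to the nearest background pixel) is
normalized by its per-nucleus maximum and subtracted from 1:

$$\rho(x, y) = 1 - \frac{D(x, y)}{\max_{nucleus} D},$$

so the deepest interior point maps to 0 and the periphery to 1. The
normalization is strictly per nucleus — never a plate-wide constant — so
nuclei of different sizes are comparable. For a disc of radius $R$ the
closed form is $D = R - r$, hence $\rho = r/R$; the tests require a mean
absolute error below $2/R$ against this closed form, with the center
exactly 0. The transform is computed per label (an adjacent nucleus counts
as background), the metric is Euclidean by default with a Manhattan option,
and a single-pixel nucleus is rejected as degenerate. The value at a spot
is read at its containing pixel without interpolation: the quantization
this introduces is below one pixel of geometry, negligible at nucleus
scale.

Radial values are binned into five shells of width 0.2, left-closed with
the last bin right-closed ([0.8, 1.0]), so that radial 1.0 belongs to shell
5. Distributions (e.g. active vs inactive alleles) are compared with the
two-sample two-sided Kolmogorov–Smirnov test (asymptotic p-values, since
pixel-quantized radial values can tie), reported with per-group mean and
sd. In pipeline summaries the "inactive" comparison group pools Inactive
and NoTranscription alleles — DNA signals without an associated RNA signal.

# The synthetic-data generator

The generator stands in for raw plate images, which are not distributed
with the package. One `SceneSpec` fully determines a field: the ground
truth (nucleus placements, expression states, spot positions) is drawn from
`seed`, and per-round noise from seeds derived from it, so an identical
spec renders bit-identical images and the *same truth in both acquisition
modes* — the basis of the mode-equivalence tests.

What it emulates, with defaults and rationale:

* **Geometry**: 512×512 px fields at 0.108 µm/px and 16-bit depth (the
  acquisition geometry at a reduced frame size, keeping micron thresholds
  realistic while tests stay fast); nuclei as smooth bright ellipses,
  equivalent radius ~N(5, 0.4) µm, eccentricity 0.2, placed without
  overlap by rejection sampling (an over-dense spec errors out).
* **Expression**: per-nucleus state drawn from `expressionProbs`
  (default 66% silent / 27% monoallelic / 7% biallelic, a predominantly
  silent gene as observed for MYC-like expression patterns); 2 DNA spot
  truths per nucleus always; 0/1/2 RNA spots offset isotropically from
  their DNA spot with sd 0.15 µm, so that essentially all true active
  pairs fall below the 1.0 µm rule and the simulated classification truth
  is unambiguous. The true offset distribution at active alleles is not an
  established quantity; 0.15 µm is a modeling choice.
* **Allele separation**: the two DNA spots keep a minimum mutual distance
  (default 2 µm) — homologous alleles occupy distinct chromosome
  territories, and the separation prevents one RNA spot from sitting
  within the activity radius of both alleles.
* **Radial placement**: the DNA-spot normalized radius is drawn as
  $\rho_{max} U^{1/\gamma}$ per expression state (default uniform,
  $\gamma = 1$, $\rho_{max} = 0.9$); $\gamma = 2$ gives the
  periphery-skewed law used to exercise the KS comparison.
* **Signal and noise**: spots are isotropic Gaussian peaks (sd 1.5 px,
  amplitude ~N(1200, 120) counts) on a 300-count background with Gaussian
  read noise (sd 30), i.e. spot SNR well above 5; nuclei at 2500 counts in
  DAPI. Noise is drawn independently per acquisition round so sequential
  DAPI pairs share structure but not pixels — registration must work on
  structure.
* **Sequential mode**: the DNA round is translated by an integer
  `interRoundShiftPx` with zero fill before noise, and the truth records
  the shift; optional "decoy" RNA spots ≥1.5 µm from any DNA spot
  exercise the Inactive branch.

What it deliberately does not emulate: PSF optics and chromatic
aberration, out-of-focus light, photobleaching, cell-cycle DNA-content
variation, segmentation-hostile nuclear textures, and z-stack acquisition
(spots are rendered directly in 2D as already-projected signals, since the
analysis operates on maximum projections and the downstream statistics are
identical). Passing recovery tests on these scenes therefore demonstrates
correctness of the *analysis logic and geometry*, not robustness to every
artifact of real microscopy.

# Problem sizes and verification strategy

The test suite and the acceptance script rerun the package's claims from
scratch at desk scale: oracle equivalence on 64×64 pairs with a ±8 px
search window; shift recovery up to ±20 px noise-free and over 10 noisy
seeds; detector precision/recall over 20 rendered fields; disc closed
forms at radii 30–60 px; a 250-field / 2000-nucleus plate for full-pipeline
recovery of expression-state fractions (judged against 3 binomial standard
deviations per class); 60 shared-truth fields per mode for
simultaneous-vs-sequential equivalence (within 2 percentage points); and
2000-draw KS discrimination with a 100-repetition type-I calibration.
These sizes were chosen so the entire suite completes in minutes on a
single CPU while keeping every binomial tolerance meaningful.

# Known limitations

* 2D only: radial positions and distances are projected quantities.
* The classical segmenter assumes DAPI-bright, roughly convex,
  well-separated nuclei; it is a contract-compatible stand-in, not a
  replacement for learned segmentation on difficult tissue.
* Single-scale LoG assumes uniform spot size; multi-scale blob detection
  is out of scope.
* Registration is translation-only; rotation, scaling and non-rigid
  deformation are not modeled.
* Transcription-intensity quantification (burst size), allele tracking
  over time, and haplotype identity are out of scope.
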