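# HTFISH

High-throughput DNA/RNA FISH image analysis with allele-level
transcription calling and radial nuclear positioning.

## What problem this solves, and for whom

Combined DNA and RNA fluorescence in situ hybridization (FISH) in 384-well
plates images, per field, a DAPI channel (nuclei), a DNA-probe channel
(the two copies of a gene locus) and an intronic RNA-probe channel
(nascent transcription sites). Because both alleles of a gene are resolved
in every nucleus, transcription can be scored per allele — and each
allele's position within the nucleus can be measured at the same time.
HTFISH is for imaging groups who run such screens (or want to validate an
analysis of them) and need a tested, scriptable pipeline for:

* **registration** of sequential RNA-round and DNA-round acquisitions via
  DAPI cross-correlation;
* **nucleus segmentation** with size/circularity quality control;
* **FISH spot detection** with a Laplacian-of-Gaussian (LoG) detector and
  sub-pixel localization;
* **allele classification** (Active / Inactive / NoTranscription) from
  DNA–RNA spot distances;
* **radial nuclear positioning** via per-nucleus distance transforms, with
  Kolmogorov–Smirnov comparison of radial distributions;
* a **seeded synthetic-image generator** with ground truth, so every stage
  is verifiable without access to raw plate images.

## The methods at the core

**Registration.** For reference image $A$ and moving image $B$, the
cross-correlation at integer displacement $(\Delta x, \Delta y)$ is
$C(\Delta x,\Delta y) = \sum_{x,y} A(x,y)\,B(x-\Delta x, y-\Delta y)$ over
the overlap region (mean-subtracted images by default); the peak gives the
translation, applied as
$B_{reg}(x,y) = B(x-\Delta x_{peak},\, y-\Delta y_{peak})$ with zero-filled
boundaries. The FFT implementation is tested to equal the direct
spatial-domain sum at every displacement.

**Spot detection.** Scale-normalized LoG filtering at a single spot scale
$\sigma$, local maxima above an Otsu-with-noise-floor threshold, 3×3
quadratic sub-pixel refinement. Spots not overlapping any segmented
nucleus are discarded.

**Allele calling.** Cells pass the gate with exactly 2 DNA spots and ≤2
RNA spots (and a QC-passing nucleus). Per DNA spot, the minimum Euclidean
distance to any RNA spot of the same cell: no RNA → `NoTranscription`;
distance < 1.0 µm (strict) → `Active`; otherwise `Inactive`.

**Radial position.** Per nucleus,
$\rho = 1 - D/\max D$ where $D$ is the Euclidean distance transform of the
nucleus mask: 0 at the deepest interior point, 1 at the periphery; binned
into five shells of width 0.2.

## Worked example

Render a synthetic field, run every analysis stage, and recover
expression states and radial positions:

```r
library(HTFISH)

spec <- SceneSpec(nNuclei = 6, seed = 7)   # 512x512 px, 0.108 um/px
sc   <- renderScene(spec)                  # images + ground truth
sc$truth
#> SceneTruth (simultaneous): 6 nuclei, 15 spots, shift (0, 0)

mask <- segmentNuclei(sc$images$DAPI)
mask
#> LabeledMask plate01/A01 f1 [single] 512x512 px, 6 nuclei

nuc   <- measureNuclei(mask)
spots <- rbind(assignSpots(detectSpots(sc$images$DNA), mask),
               assignSpots(detectSpots(sc$images$RNA), mask))
cells <- summarizeCells(nuc, spots)
al    <- annotateRadial(classifyAlleles(cells, spots), mask)
head(al[, c("nucleus_label", "dna_spot_id", "min_rna_distance_um",
            "status", "radial", "shell")])
#>   nucleus_label dna_spot_id min_rna_distance_um          status    radial shell
#> 1             1           6                  NA NoTranscription 0.6879097     4
#> 2             1          12                  NA NoTranscription 0.8233766     5
#> 3             2           1                  NA NoTranscription 0.2792405     2
#> 4             2           4                  NA NoTranscription 0.7517182     4
#> 5             3           5          0.01456524          Active 0.3303802     2
#> 6             3           9          3.55177186        Inactive 0.4400531     3

recoverStateFractions(al)
#>   biallelic monoallelic      silent
#>         0.0         0.5         0.5
```

Each row of `al` is one allele: its minimum DNA–RNA distance in microns
decides the activity call, and `radial`/`shell` give its normalized
nuclear position (0 = center, 1 = periphery). With six nuclei the state
fractions are coarse; the same computation over a 2000-nucleus plate
recovers the generator's expression probabilities to within binomial
noise (see below). Radial distributions of groups of alleles are compared
with `compareRadial(active, inactive)`, a two-sided two-sample KS test.

The whole chain — including registration for two-round acquisitions — is
also available as one call:

```r
fields <- lapply(1:4, function(i)
  renderScene(SceneSpec(nNuclei = 8, interRoundShiftPx = c(7L, -4L),
                        seed = i), mode = "sequential",
              well = sprintf("B%02d", i))$images)
res <- runPipeline(htfishConfig("sequential"), fields = fields,
                   outDir = "results_seq")
res$shifts          # estimated (7, -4) per field
res$summary         # plate-level summary (also written as CSV + markdown)
```

`runPipeline` can equally consume a plate directory written by
`writePlate()` (TIFFs + `manifest.csv`) and writes per-well flat CSV
tables — one nucleus file per well, one spot file per well and channel —
plus allele tables, shift logs, a radial comparison and a summary.

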