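---
title: "Ratiometric quantification of mitophagy with mitocount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric quantification of mitophagy with mitocount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocount)
```

## The biological readout and its model

Tandem mCherry–GFP mitophagy reporters exploit the acid lability of GFP:
both fluorophores are attached to an outer-mitochondrial-membrane anchor,
and while mitochondria reside in the cytosol the two channels report the
same reporter distribution. When a mitochondrion is delivered to a lysosome
the low pH quenches GFP but not mCherry, so the resulting *mitolysosome* is
a "red-only" punctum. The quantity of interest is the number, area and size
of these puncta per cell or tissue region.

`mitocount` models this directly on the pixel-wise intensity ratio
$R = I_{red}/I_{green}$: inside healthy mitochondria and (noisy) background
$R \approx 1$ under typical acquisition settings, while mitolysosome pixels
have $R \gg 1$. Detection is therefore peak finding on the ratio image, with
two guards: a *prominence* criterion that separates genuine peaks from ratio
texture, and a *red-intensity* criterion that rejects high-ratio pixels in
dim background, where the ratio of two small noisy numbers is meaningless.

## The pipeline, step by step

1. **Median smoothing** (`median_smooth()`). Both channels are filtered with
   the circular kernel $\{(dx,dy): dx^2+dy^2 \le r^2+1\}$ — the ImageJ
   rank-filter convention, so radius 1 is the full $3\times3$ window and
   radius 2 covers 21 pixels — with edge replication at the borders. Radius
   0 disables smoothing. The default radius of 1 suits well-sampled
   widefield data; oversampled confocal data may need 2, and values above
   2–3 blur genuine puncta away.

2. **Ratio image** (`compute_ratio()`). Smoothed red over smoothed green,
   pixel-wise. Division by zero is resolved per image: where green is 0 and
   red positive, the pixel receives the maximum finite ratio in the image
   plus twice the prominence, which makes it finite (the peak search needs a
   finite raster) yet guaranteed to out-prominence every genuine peak;
   where both channels are 0 the ratio is defined as 0. The guard value is
   recomputed per image so it adapts to the image's own ratio range.

3. **Peak detection** (`find_maxima()`). ImageJ *Find Maxima* semantics
   under 8-connectivity: a local maximum is reported iff every path from it
   to strictly higher terrain drops below its value minus the prominence
   (`ratio_thresh`). Equal-valued plateaus are one candidate; equal-valued
   maxima connected within tolerance merge into a single peak. The reported
   pixel is the lexicographically smallest $(y, x)$ plateau member — a
   deterministic tie-break. A constant image has no maxima; border pixels
   are eligible. `ratio_thresh` is interpreted as this prominence ("noise
   tolerance"), not as an absolute ratio cutoff: working values (0.4–0.6)
   sit *below* the ratio baseline of ~1, which only makes sense as a
   relative height criterion. Lowering it towards 0.2 floods the count
   with background ratio texture; raising it prunes the count to the most
   prominent puncta — the monotonicity property tests pin down exactly this
   behaviour.

4. **Red-intensity filtering** (`compute_red_threshold()`,
   `filter_peaks()`). The threshold is $\mu + k\sigma$ of the *smoothed* red
   channel over the *entire image* (not per ROI), with the population
   standard deviation (divide by $N$), matching ImageJ image statistics.
   Computing it on the smoothed channel keeps the threshold and the peak
   intensities in the same domain. $k$ (`red_stddev_offset`, default 0) may
   be negative; raising it suppresses dim false positives at the cost of
   dim true mitolysosomes.

5. **Mitophagy mask** (`build_mask()`). Each accepted peak floods the
   8-connected set of pixels whose ratio is within the prominence of the
   peak value ("maxima within tolerance"), the union is intersected with
   the red-threshold set, and areas are measured on the result. This ties
   mask objects to counted peaks, so area statistics and counts stay
   mutually consistent. The alternative reading — a single global threshold
   of the ratio image — would detach the mask from the counted peaks; we
   chose the flood construction and note one consequence: because the flood
   level is *peak value minus prominence*, a larger prominence can enlarge
   individual mask objects even as it removes peaks, so mask area is not
   monotone in the prominence (counts are). Area *is* monotone in the red
   offset.

6. **Measurements** (`measure_roi()`, `measure_image()`,
   `write_results_csv()`). Intensity means and totals use the *raw*
   channels — they are reporter-content readouts of the source image, and
   smoothing exists only to stabilise detection. Counts use the accepted
   peaks inside the rasterized ROI; areas use mask pixels inside the ROI
   times the squared pixel size. Mean mitolysosome size divides mask area
   by *peak* count (not connected-component count), and is reported as 0
   when the count is 0 so CSVs stay numeric. Overlapping ROIs are measured
   independently, with a warning when a peak is claimed twice. The CSV
   carries the standard 18-column header with areas in µm².

## Parameters at a glance

| parameter | unit | default | effect |
|---|---|---|---|
| `smooth_radius` | pixels | 1 | noise suppression vs. blurring of puncta |
| `ratio_thresh` | ratio units | 0.5 | peak prominence; lower → more (noisier) counts |
| `red_stddev_offset` | SDs | 0 | red threshold $\mu + k\sigma$; higher → stricter |
| `pixel_size_um` | µm/pixel | from TIFF | scales all µm² outputs |

Missing TIFF calibration falls back to 1 µm/pixel *with a warning* — areas
in the output are then in pixel units, and silently wrong units are worse
than flagged defaults.

## Coordinate and file conventions

Pixel coordinates are 0-based with $x$ = column, $y$ = row; polygon
vertices live in pixel units with the origin at the top-left corner of
pixel $(0,0)$, and membership is decided by the even–odd rule at pixel
centres $(x+0.5, y+0.5)$ — an unambiguous, testable rasterization that
closely matches ImageJ's. Supported ROI sources are ImageJ polygon,
freehand, traced, rectangle and oval selections (`.roi`, `.zip`) and label
masks; line and point ROIs are rejected by name. TIFF reading accepts
interleaved stacks, ImageJ hyperstacks and single-page multi-sample files.
Calibrated TIFF output (ratio images, the synthetic suite) is written by a
small built-in baseline-TIFF writer because the CRAN `tiff` package cannot
emit resolution or description tags; the ImageJ ROI reader/writer and the
stored-ZIP container writer are likewise built in, there being no R package
for those formats. The ratio image is written as 32-bit float (read-back is
bit-exact at float32 precision), the mask as 8-bit 0/255.

## The synthetic-data generator

`render_scene()` emulates the features the method actually keys on: cell
regions where red and green are spatially correlated at a common base
intensity (ratio ≈ 1); hard-disk puncta carrying reporter amplitude $A$
where red becomes $B + A$ and green $(B + A)(1 - q)$ for quench fraction
$q$ — so the centre ratio is $1/(1-q)$, and $q = 0$ reproduces the
bafilomycin-A1 control in which de-quenched GFP makes puncta vanish from
the ratio image; a darker background; additive Gaussian noise clipped at 0;
and integer quantization, as a real detector would apply. All randomness
flows from one seed and rendering is bit-reproducible.

Hard disks are used instead of Gaussian spots because their footprints are
exactly enumerable, so expected mask areas are analytic. The benchmark
defaults were fixed once as a plausible widefield scenario: 192×192 px at
0.16 µm/pixel, background 100 DN, cell base 2000 DN, amplitude 2000 DN,
quench 0.9 (centre ratio 10), 5–50 puncta per induced image and none in
controls, separations of at least four radii. The default punctum radius is
2.5 px (≈0.8 µm diameter): the 21-pixel digital disk at that radius is
*invariant under the radius-1 median kernel*, so the noiseless expected
mask equals the analytic footprint exactly, which is what makes exact-area
assertions possible. Noise defaults to 0; noisy property tests pass
`noise_sd` explicitly (120 DN, i.e. 6% of the cell intensity, for the
monotonicity sweeps).

What the generator does **not** emulate: optics (no PSF convolution, so
real puncta have soft edges), photobleaching, chromatic shift, Poisson
statistics, expression heterogeneity, or tissue texture. Passing the
synthetic benchmarks therefore demonstrates the *algorithmic* correctness
of detection and measurement — not that any particular threshold is right
for a given microscope, which remains a per-experiment tuning task.

## Numerical and degenerate-input choices

- Population (÷N) standard deviation in the red threshold; statistics over
  the whole image.
- Prominence comparisons are strict (`> tolerance`); the flood boundary is
  inclusive (`≥ peak − tolerance`).
- Peaks are not merged by distance; every prominence-accepted maximum
  counts once (no minimum-separation rule).
- Degenerate (zero-area) polygon ROIs rasterize to 0 pixels with a warning;
  ROIs entirely outside the image raise an error; empty ROI containers
  raise "no ROIs found".
- Constant rasters yield no peaks; an empty peak set yields an all-false
  mask and all-zero measurement columns.
- Detection is invariant to a global gain applied to both channels: the
  ratio is unchanged and the adaptive red threshold scales with the data.

## Problem sizes used by the checks

The test-suite and the acceptance script verify the maxima finder against a
brute-force level-set prominence oracle on 200 random rasters up to 32×32
(values 0–20) plus ~24 constructed ridge/plateau/saddle cases; detection
and measurement against analytic ground truth on 10-image noiseless suites
(~250–300 puncta); monotonicity on 20 noisy images; and the median filter
against a per-pixel sort oracle on 50 16×16 rasters. These sizes give exact,
reproducible expectations while keeping a full run in the tens of seconds.

## Known limitations

- 2-D planes only; z-stacks must be projected or analysed per slice, and
  frames of time-lapse data are analysed independently.
- No watershed splitting of touching mitolysosomes; two merged objects
  under one peak are counted once, and mean size averages over peaks.
- No background subtraction or flat-field correction — acquisition problems
  (high background, bleaching, saturation) should be fixed upstream; the
  tool warns when it can recognise them (saturated channels, red signal
  barely above background, missing calibration).
- ROIs embedded as TIFF overlays are not read; export them as `.roi`/`.zip`
  or label masks. Batch mode pairs images and ROI containers by basename.
- Sub-pixel ROI vertices are honoured when present in the file, but only
  integer-vertex round-trips are guaranteed bit-exact.
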