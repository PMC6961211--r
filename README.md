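# mitocount

Quantifies **mitophagy** — the autophagic delivery of mitochondria to
lysosomes — from two-channel fluorescence images of cells or tissue
expressing a tandem mCherry–GFP mitophagy reporter, and from any similar
dual-colour pH-biosensor. It is a scriptable R re-implementation of the
ratiometric "red-only puncta" counting workflow popularised as a FIJI macro,
for people who want the same measurements in a reproducible, testable,
batch-friendly form: imaging scientists, cell biologists and image-analysis
core facilities.

## The method

Outside lysosomes the reporter fluoresces in both channels, so the pixel-wise
intensity ratio

```
R(x, y) = I_mCherry(x, y) / I_GFP(x, y)
```

sits close to 1. Lysosomal pH quenches GFP but not mCherry, so a
**mitolysosome** appears as a punctum of elevated ratio. The pipeline is:

1. **Median smoothing** of both channels with the ImageJ circular kernel
   `{(dx, dy) : dx² + dy² ≤ r² + 1}` (radius *r* = `smoothRad`, default 1);
2. **Ratio image** `R = red / green` (finite everywhere, with a documented
   sentinel where green = 0);
3. **Peak detection** by topographic prominence (ImageJ *Find Maxima*
   semantics, 8-connectivity): a maximum counts iff it stands more than
   `ratioThresh` (default 0.5) above the highest saddle connecting it to
   higher terrain;
4. **Red-intensity filtering** with the adaptive threshold
   `mean(red) + k·sd(red)` computed over the whole smoothed red channel
   (`k` = `redStdDev` offset, default 0), removing spurious high-ratio peaks
   in dim background;
5. **Mitophagy mask**: each accepted peak is flooded over the connected
   pixels within `ratioThresh` of its ratio value, intersected with the red
   threshold — areas and mean mitolysosome sizes come from this mask;
6. **Per-ROI measurements** (18-column CSV): region area, mean channel
   intensities, mitolysosome count, count per µm², count per unit green
   (a proxy for mitochondrial content), mask areas and the echoed
   parameters.

Regions of interest come from ImageJ ROI files (`.roi`, `.zip`) or label
masks; images are multi-channel TIFFs with micron calibration.

## Worked example

The package ships a synthetic-scene generator with exact ground truth, so
the whole pipeline can be exercised without microscope data:

```r
library(mitocount)
dir <- file.path(tempdir(), "demo")
suite <- make_benchmark_suite(dir, n_images = 2, seed = 1)   # induced + control
res <- run_batch(dir, detection_params(ratio_thresh = 0.5, smooth_radius = 1))
res$results[, c("image", "cell_roi", "n_mitolysosomes", "ml_pct_area")]
```

which logs and prints:

```
'img001_induced': red threshold = 1583.59, 8 peak(s)
'img002_control': red threshold = 1574.48, 0 peak(s)
           image cell_roi cell_area_um2 n_mitolysosomes ml_total_area_um2 ml_pct_area
  img001_induced   cell01         366.2               4              2.15      0.5872
  img001_induced   cell02         366.2               4              2.15      0.5872
  img002_control   cell01         366.2               0              0.00      0.0000
  img002_control   cell02         366.2               0              0.00      0.0000
```

The "induced" image carries 8 ground-truth puncta (4 per cell) and all 8 are
recovered; the control image has none and none are reported. Per cell,
`cell_area_um2` is the ROI area (366 µm² at 0.16 µm/pixel),
`ml_total_area_um2` the mask area attributed to mitolysosomes and
`ml_pct_area` the percentage of the cell they occupy. Alongside the combined
`results.csv`, the batch run writes per image a 32-bit float ratio TIFF, an
8-bit mitophagy-mask TIFF and an RGB overlay PNG with ROI outlines and peak
markers.

The same operations are available from a shell:

```sh
Rscript inst/cli/mitocount.R simulate --out demo --n-images 2 --seed 1
Rscript inst/cli/mitocount.R batch demo --ratio-thresh 0.5 --red-channel 1 --green-channel 2
Rscript inst/cli/mitocount.R count demo/img001_induced.tif demo/img001_induced.zip
```

## Layout

- `R/`, `src/` — implementation (S3 classes; the median filter, prominence
  maxima and flood fills are in C++ via Rcpp);
- `inst/cli/mitocount.R` — command-line front end (`count`, `batch`,
  `simulate`);
- `tests/testthat/` — unit, property and acceptance tests with brute-force
  oracles;
- `vignettes/mitophagy-quantification.Rmd` — the methods vignette: model,
  parameters, numerical choices, limitations.
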