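# echoplanim

Decision support for mitral stenosis from 3D transesophageal echocardiogram
(TEE) videos, for cardiologists and imaging researchers who want a
reproducible, fully scriptable alternative to manual workstation planimetry.

Mitral stenosis is the failure of the mitral valve to open completely; its
planimetric severity criterion is the **mitral valve area (MVA)** — the
orifice area at maximum diastolic opening, in cm². `echoplanim` implements
two complementary arms:

1. **A digital-image-processing (DIP) planimetry engine.** Every frame of an
   AVI echocardiogram is converted to grayscale by luminance,

   *L* = 0.2989 *R* + 0.5870 *G* + 0.1140 *B*,

   then binarised by a single-band fixed threshold (*v_out* = 1 iff
   *v_in* > *t*). In an en-face TEE render the tissue is brightly coloured
   and the orifice is dark, so the valve opening appears as the largest
   dark region fully enclosed by bright pixels. Its area in cm² is the
   enclosed pixel count times the per-pixel area, which is calibrated from
   vendor on-screen markers (paired green ruler dots for Philips exports, a
   scale line for GE). Thresholds *t* = 10, 11, …, 30 are scanned
   sequentially, each selecting the frame with the largest orifice; the scan
   stops early when the best-contour perimeter jumps by more than 1.0 cm
   between consecutive thresholds (an instability guard), in which case the
   penultimate threshold is selected. The resulting MVA is graded:

   | MVA (cm²)         | grade       |
   |-------------------|-------------|
   | ≥ 4.0             | no stenosis |
   | 1.5 < a < 4.0     | mild        |
   | 1.0 ≤ a ≤ 1.5     | moderate    |
   | < 1.0             | severe      |

2. **A screening CNN.** Four conv(3×3, ReLU) + max-pool stages with filter
   counts 32→64→128→256, a dense layer of 512 units and a 2-unit softmax
   head, trained with Adam (batch 100, ≤ 10 epochs, early stopping on test
   loss) on augmented video frames (rotations ≤ 40°, shifts ≤ 20%, shear,
   zoom, horizontal flips, nearest-neighbour fill; six augmented copies per
   frame; 70/30 image split plus whole held-out videos). It gives a binary
   has-/no-stenosis verdict per video by majority vote over frames.

Because clinical TEE recordings cannot be redistributed, the package ships a
**phantom generator**: synthetic echocardiogram-like AVI videos with a
coloured tissue disk, a central orifice following a raised-cosine
open–close cycle with a known diastolic maximum, calibration markers and
optional speckle noise — with analytic ground truth for every frame. All
I/O (a minimal lossless uncompressed AVI reader/writer) and all numerics
(including the CNN's im2col/GEMM kernels) are self-contained.

## Worked example

```r
library(echoplanim)

# a synthetic exam with a known diastolic MVA of 2.5 cm^2
sp <- phantom_spec(diastolic_mva_cm2 = 2.5, marker_dialect = "philips", seed = 7)
video <- tempfile(fileext = ".avi")
generate_phantom(sp, video)

report <- run_dip(video, calib_mode = "philips")
print(report)
#> <dip_report: filea8d39f311f3.avi>
#>   MVA 2.503 cm2 at threshold 30 (frame 20) -> mild

glance(report$scan)
#> # A tibble: 1 × 6
#>   selected_threshold selected_frame_index mva_cm2 grade stop_reason  n_thresholds
#>                <int>                <int>   <dbl> <fct> <chr>               <int>
#> 1                 30                   20    2.50 mild  threshold_c…           21
```

The engine measured 2.503 cm² against a ground truth of 2.5 cm² (the 0.1%
difference is rasterisation), found the diastolic peak at frame 20 of 40,
scanned all 21 thresholds without tripping the perimeter guard, and graded
the exam as mild stenosis. `tidy(report$scan)` exposes the per-threshold
trace and `autoplot(report$scan)` plots it.

Grading a cohort of MVA measurements:

```r
summarize_cohort(mva_reference_cohort()$mva_cm2)
#> # A tibble: 4 × 4
#>   grade           n fraction percent
#>   <fct>       <int>    <dbl>   <dbl>
#> 1 no_stenosis     8    0.267    26.7
#> 2 mild            8    0.267    26.7
#> 3 moderate        4    0.133    13.3
#> 4 severe         10    0.333    33.3
```

For the CNN arm, see `generate_cohort()`, `augment_videos()`,
`split_dataset()`, `build_model()`, `cnn_train()`, `cnn_evaluate()` and
`predict_video()`; `run_compare()` reports the DIP and CNN verdicts side by
side and flags disagreements. A thin CLI over the same functions is
installed at `inst/scripts/planim` (subcommands `measure`, `grade`,
`cohort`, `phantom`, `predict`, `compare`).

Note on the split: augmented siblings of one frame may land on both sides
of the 70/30 image-level split, so held-out *videos* (excluded entirely)
are the leak-free evaluation set.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline cohort figures
from scratch — it loads the packaged 30-exam reference measurements, runs
`classify_mva()` over them, and writes the per-grade exam counts as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

- The AVI reader supports the package's own uncompressed 24-bit DIB
  dialect; vendor-compressed exports must be transcoded first.
- Phantoms validate the measurement chain, not clinical performance: they
  lack true speckle statistics, shadowing and anatomical variability (see
  the methods vignette).
- The CNN is a desk-scale screener; it reports only a binary verdict and,
  as the comparison arm shows, can miss mild disease that planimetry
  measures directly.
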