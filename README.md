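# plugtray

Machine-vision grading of potted seedlings in plug trays.

Vegetable nurseries grow seedlings in molded trays (here 3 rows × 7 columns
= 21 cells), and an automatic transplanter must decide, per cell, whether
the plant is healthy enough to grasp, replace, or discard. `plugtray`
implements the vision side of that decision for overhead RGB tray images,
and ships a synthetic tray renderer with exact ground truth so the whole
pipeline is testable without any camera data.

## The method

**Preprocessing.** Leaves, substrate and tray are separated chromatically by
the linear indices

    TG = (3G − R − B) / 3        (enhances green: leaves)
    TR = (3R − G − B) / 3        (enhances red: the tray)

plus a standard luma grayscale `Y = 0.2989 R + 0.5870 G + 0.1141 B`. Index
images are min–max rescaled to integer levels 0..255 before histogramming.

**Segmentation.** A threshold pair `T1 < T2` is chosen to maximize the
Kapur-style summed within-class entropy of the gray-level histogram

    F(T1, T2) = Σ_k H(class k),   classes [0,T1], (T1,T2], (T2,255]

optimized by a genetic algorithm over 16-bit chromosomes (8 bits per
threshold; population 21, ≤100 generations, crossover 0.6, mutation 0.03,
roulette selection with linear fitness scaling and elitism). An exhaustive
search over all 32,640 pairs (`brute_force_thresholds()`) provides the exact
reference. The mask is the top entropy class (leaf) by default.

**Denoising.** The binary mask is cleaned by BM3D: similar 8×8 blocks are
grouped by the step-normalized distance `d = ‖X_P − X_Q‖ / h < τ_d`,
hard-thresholded in a 3D orthonormal DCT domain at `λ_3D σ`, and overlapping
estimates are averaged with sparsity weights `1/N_P` (or energy weights
`E/(E+σ²)` in the optional second pass). This removes isolated
misclassified pixels and fills small holes in leaf regions.

**Grading.** Each cell's leaf pixel count `P` gives a physical leaf area
`M = K·P` (`K` = mm² per pixel from tray calibration) and a dimensionless
leaf-cover ratio `F` = leaf pixels / cell pixels. Grades, with thresholds
calibrated on 20 groups of pepper seedlings (2,100 plants):

| rule | grade |
|---|---|
| `F < 0.015` | empty cell |
| `F > 0.20` | healthy |
| `0.16 ≤ F ≤ 0.20` | sub-healthy |
| otherwise | poor |

Each cell is reported with transplanter coordinates on the odd lattice
`x = 2·col − 1`, `y = 2·row − 1` (origin at the tray's upper-left corner,
X rightward, Y downward).

## Worked example

```r
library(plugtray)

# a synthetic 21-cell tray: 16 healthy cells, plus one cell each at
# sub-healthy (0.18), poor (0.10, 0.05) and empty (0) cover levels
spec <- synth_spec(
  per_cell_f = c(rep(0.30, 10), 0.18, 0.18, 0.10, 0.05, 0, rep(0.25, 6)),
  seed = 11
)
tray <- generate_tray(spec)

res <- run_pipeline(tray$image, pipeline_config(seed = 5))
res
#> <tray_result> 21 cells | thresholds (t1, t2) = (63, 115)
#>   healthy 16 | sub_healthy 2 | poor 2 | empty 1

summary(res)
#> healthy      16  (1,1) (3,1) (5,1) (7,1) (9,1) (11,1) (13,1) (1,3) (3,3) (5,3) (3,5) (5,5) (7,5) (9,5) (11,5) (13,5)
#> sub_healthy   2  (7,3) (9,3)
#> poor          2  (11,3) (13,3)
#> empty         1  (1,5)

head(tidy(res), 3)
#> # A tibble: 3 × 9
#>     row   col     x     y pixel_count leaf_area_mm2     f label   cell_px
#>   <int> <int> <int> <int>       <int>         <dbl> <dbl> <ord>     <int>
#> 1     1     1     1     1         693         2166. 0.301 healthy    2304
#> 2     1     2     3     1         695         2172. 0.302 healthy    2304
#> 3     1     3     5     1         672         2100  0.292 healthy    2304
```

The genetic algorithm picked thresholds (63, 115) on the quantized green
index; every cell's grade matches the renderer's ground truth, and the
summary lists the coordinates a transplanter would visit per grade.
`autoplot(res)` draws the tray as a tile map colored by grade, and
`glance(res)` returns the one-row run summary.

Grading thresholds themselves come from calibration data:

```r
calibrate_thresholds(pepper_threshold_groups())
#> <f_calibration>
#>   pooled: f_max = 0.25, f_avg = 0.20, f_min = 0.15 (20 groups)
```

## Command line

A thin CLI over the same functions lives at `inst/cli/plugtray`
(`system.file("cli", "plugtray", package = "plugtray")`), with subcommands
`synth`, `segment`, `denoise`, `identify`, `calibrate`, `eval`:

```sh
plugtray synth    --f 0.3 --seed 4 --out tray.png --truth truth.json
plugtray identify --image tray.png --seed 4 --out results.csv --json summary.json
```

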