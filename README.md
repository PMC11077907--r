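# dklstats

Cone-opponent color statistics for comparing image corpora.

`dklstats` asks a simple quantitative question of two collections of images:
**are warm-colored (object-like) regions relatively more saturated than
cool-colored (background-like) regions in one corpus than in the other?**
The question arises in visual psychophysics when comparing depictions
(e.g. still-life paintings of fruit) against photographs of comparable
scenes: the memory-color effect predicts that painted objects carry an
excess of chromatic contrast relative to their backgrounds, because familiar
objects are remembered — and rendered — more saturated than they appear.
The package provides the full measurement pipeline for that comparison,
plus a seeded synthetic still-life generator with exact ground truth so the
whole chain is testable without any image downloads.

## The statistics it computes

Pixels are mapped from sRGB into the cone-opponent DKL space: linear RGB →
CIE XYZ → LMS cone excitations, expressed as opponent contrasts relative to
an adapting mid-gray background,

- an achromatic axis `L/M/S` (L+M excitation difference from background),
- a chromatic `L/M` axis (teal ↔ cherry; L−M, nulled for achromatic input),
- a chromatic `S` axis (violet ↔ lime; S−(L+M), likewise nulled),

with each axis scaled so the RGB display gamut maps into `[-2, 2]`
(the mid-gray background sits at the origin). From there:

1. **Joint histograms** — per-image 128×128 counts over each pair of DKL
   axes, normalized by image pixel count; corpus summaries are binwise means.
   A *chromogram* colors each occupied bin with the mean color of its pixels.
2. **Chromatic contrast curves** — each bin's chromatic contrast is its
   center's distance to the origin, rounded to 4 decimals (1,464 distinct
   levels on the default grid). For a quadrant subset Q the curve is
   `c_Q(r) = (1/|Q|) * sum of histogram mass of Q-bins at contrast r`,
   so subsets of different sizes are comparable (e.g. the warm quadrant Q1
   against Q2+Q3+Q4 combined). Curves are smoothed for display by a
   unit-sum Gaussian (σ = 10 samples).
3. **Percentile bootstrap bands** — N per-image curves are resampled with
   replacement 1,000 times; at each contrast level the 25th and 975th sorted
   resampled means bound the 95% band.
4. **Warm-excess statistic** — the difference in density-weighted mean
   contrast between a quadrant subset and its complement:
   `W = E_Q[r] - E_rest[r]`. Positive when the warm quadrant carries
   relatively more high-contrast mass. The same statistic applied to the
   "blue" quadrant of the S-vs-achromatic plane serves as a control.
5. **Local CIELUV differences** — after a central square crop and bicubic
   resize to 256×256, each image yields its mean 8-neighbor Euclidean
   distance in the (u′, v′) chromaticity plane (chromatic) and in the L
   plane (achromatic), with per-corpus Pearson correlations between the two.

## Worked example

Generate two small synthetic corpora — a "painting-like" condition whose
fruit blobs get a warm-axis saturation gain of 1.5, and a "photo-like"
condition with gain 1.15 — and run the full analysis:

```r
library(dklstats)
root <- tempfile(); dir.create(root)
generate_corpus(8, condition = "painting", seed = 1,
                params = still_life_params(width = 128, height = 128),
                out_dir = file.path(root, "paintings"))
generate_corpus(8, condition = "photo", seed = 2,
                params = still_life_params(width = 128, height = 128),
                out_dir = file.path(root, "photos"))
cfg <- run_config(file.path(root, "paintings"), file.path(root, "photos"),
                  labels = c("painting_like", "photo_like"),
                  n_boot = 1000, seed = 7, output_dir = file.path(root, "out"),
                  local_diff_side = 128L)
report <- run_analysis(cfg)
print(report)
```

```
Two-corpus DKL chromatic-contrast analysis
  painting_like: 8 images   photo_like: 8 images
  excess_lm_s      A=+0.0834  B=+0.0255  diff=+0.0579
  excess_lm_ach    A=-0.0657  B=-0.1278  diff=+0.0622
  blue_control     A=+0.1923  B=+0.2061  diff=-0.0137
  local-difference correlations:
         group n          r         p
 painting_like 8 -0.5553726 0.1529863
    photo_like 8  0.6161481 0.1038133
```

Reading the numbers: in the isoluminant plane (`excess_lm_s`) the warm
quadrant's mass sits at higher chromatic contrast than the rest in both
corpora (both positive), and the excess is larger for the painting-like
corpus (`diff = +0.058`) — the injected effect, recovered. The same ordering
appears in the L/M-vs-achromatic plane. The blue-quadrant control
(`blue_control`) shows no comparable between-corpus difference, as the
generator injects no cool-quadrant effect. With only 8 images per corpus the
local-difference correlations are noisy; they are reported with their
per-corpus sample sizes and p-values.

`run_analysis()` also writes per-plane histogram and curve CSVs, PNG
figures (gray-level joint histograms; quadrant curves with their bootstrap
bands; the local-difference scatter), and a `report.json` with every
headline number, all reproducible byte-for-byte under the same seed.

A shell front end covers the same ground:

```sh
Rscript inst/scripts/dklstats synth --out corpora/a --n 20 --seed 1 --condition painting
Rscript inst/scripts/dklstats synth --out corpora/b --n 20 --seed 2 --condition photo
Rscript inst/scripts/dklstats analyze --a corpora/a --b corpora/b --out results --seed 7
```

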