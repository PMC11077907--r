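---
title: "Measuring warm-versus-cool chromatic contrast in image corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring warm-versus-cool chromatic contrast in image corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dklstats)
```

## The measurement problem

Given two corpora of RGB images, the package quantifies whether warm-colored
pixels (reds, oranges, yellows — a practical proxy for depicted objects such
as fruit) are *relatively* more saturated than cool-colored pixels (a proxy
for backgrounds) in one corpus than in the other. "Saturation" here is
radial chromatic contrast: the distance of a pixel's chromatic coordinates
from the adapting-background origin of the cone-opponent DKL plane. The
comparison is deliberately relative — quadrant against quadrant within each
image set — so it is insensitive to overall differences in colorfulness,
exposure, or image size between the corpora.

## Color model

### From sRGB to DKL

Inputs are assumed sRGB-encoded. Pixels are decoded with the standard
piecewise electro-optical function, taken to CIE XYZ (IEC sRGB primaries,
D65 white), then to LMS cone excitations (Hunt–Pointer–Estévez,
D65-normalized). Opponent coordinates are excitation differences relative
to a fixed adapting background, by default the mid-gray with linear RGB
(0.5, 0.5, 0.5):

* achromatic: $\Delta L + \Delta M$;
* L/M (teal–cherry): $\Delta L - k\,\Delta M$;
* S (violet–lime): $\Delta S - k_2(\Delta L + \Delta M)$.

The weights $k$ and $k_2$ are computed from the configured matrices so that
the achromatic direction ($R=G=B$) is annihilated *exactly*: any neutral
pixel has zero chromatic signal to machine precision, whatever cone
fundamentals are supplied. This matters because the downstream statistics
bin pixels by chromatic sign and radius; a leaky opponent axis would smear
neutral backgrounds across quadrants.

Because the analysis is comparative, its conclusions are robust to the
exact choice of fundamentals; every matrix, the background, and the axis
polarities and scales live in `dkl_config()` and can be overridden from a
flat key–value file (`read_dkl_config()`).

### Axis polarity and scaling

Polarity defaults put cherry/red at $+L/M$ and lime/yellow at $+S$, so the
warm red–orange–yellow hues occupy quadrant Q1 $(+,+)$ of the isoluminant
plane and blue falls at negative S. (Reading the conventional axis names
"teal–cherry" and "violet–lime" as negative-to-positive pairs gives exactly
this orientation; it is configurable.)

Each axis is scaled so that the most extreme corner of the RGB cube maps to
magnitude 2 (`rgb_cube_projection()` verifies the whole gamut fits). This
*gamut calibration* guarantees that no in-gamut pixel can fall outside the
histogram range, so the out-of-range counter in every histogram should read
zero for ordinary images; it exists as a tripwire for misconfigured
transforms and non-sRGB inputs.

## Joint histograms and contrast curves

Histograms use 128×128 equal-width bins on $[-2,2]^2$, half-open with the
last bin closed, normalized by the image's total pixel count so images of
different sizes contribute equally. Corpus histograms are unweighted
binwise means over images (not pixel-pooled — each image is one sample).

Each bin's chromatic contrast is the Euclidean distance of its *center*
from the origin, rounded to **4 decimal places**, half away from zero. On
the default grid this yields exactly 1,464 distinct contrast levels, and —
because bin centers sit at odd multiples of half the bin width — every
quadrant realizes the same level set and no center lies on an axis, so
quadrant membership by strict sign is total (asserted at construction).

The contrast curve of a quadrant subset $Q$ is

$$ c_Q(r) = \frac{1}{|Q|}\sum_{b \in Q,\; \rho(b)=r} h(b), $$

the histogram mass at level $r$ divided by the *number of grid bins* in
$Q$. The per-bin normalization is what makes Q1 comparable against the
three other quadrants combined. Curves are computed unsmoothed; for display
(and only for display) they are convolved with a unit-sum Gaussian of
σ = 10 samples, truncated at 4σ and renormalized, with a reflecting
boundary. Reflection was chosen over zero-padding because the mass of
typical images concentrates at low contrast, exactly where a zero-padded
kernel would bleed mass off the curve; the unit-sum kernel then preserves
total mass to 1e-9. Normalization precedes smoothing throughout.

## The warm-excess statistic

The package reduces a pair of quadrant curves to one number: the difference
of density-weighted mean contrasts,

$$ W = \frac{\sum_r r\,c_Q(r)}{\sum_r c_Q(r)} -
       \frac{\sum_r r\,c_{\bar Q}(r)}{\sum_r c_{\bar Q}(r)}. $$

$W$ is zero whenever the two profiles have equal mean radial contrast
(regardless of how much mass each quadrant holds), positive when the chosen
quadrant's mass sits farther out, and strictly increasing under any
saturation boost confined to that quadrant. A raw signed area between the
curves was considered and rejected: on the strongly non-uniform 1,464-level
grid a trapezoid area is dominated by local level spacing rather than by
mass displacement, and a plain sum of differences measures only relative
mass fractions, not saturation. The normalized first moment has the three
properties the analysis actually needs.

The same statistic evaluated for the "blue" quadrant (Q3 of the
S-vs-achromatic plane: $S<0$, dark) is reported as a control: a saturation
preference specific to warm object colors should not reproduce there.

## Bootstrap bands

Confidence bands for mean curves use the percentile bootstrap: resample the
$N$ per-image curves with replacement $N$ at a time, 1,000 times; at each
contrast level sort the resampled means and take the 25th and 975th values
for a 95% band. "Sorting the curves" is interpreted pointwise per level —
the only reading that yields a well-defined envelope, since no total order
on whole curves is available. Bootstrapping operates on unsmoothed
per-image curves; the mean and both bounds are then smoothed identically
for display. Resampling draws one multinomial count vector per replicate,
and a single documented seed makes bands bit-reproducible.

## Local chromatic and achromatic differences

Independently of the DKL analysis, each image is centrally cropped to a
square (offsets floored), resized to 256×256 by bicubic interpolation, and
converted to CIELUV chromaticity–luminance form: $u' = 4X/(X+15Y+3Z)$,
$v' = 9Y/(X+15Y+3Z)$, with black mapped to the white-point $(u',v')$ to
avoid 0/0. The resampler is a separable Keys cubic (a = −0.5) with the
kernel widened by the inverse scale when downsampling and borders
replicated — written in-package because no installed R imaging package
offers a cubic filter. The L channel is relative luminance $Y \in [0,1]$ by
default, with CIE $L^*$ available by option; the named conversion chain
implies the $(u',v',L)$ triple, but since a monotone re-mapping of L changes
the correlation analysis slightly, the choice is exposed rather than fixed.

For every interior pixel the chromatic difference is the mean Euclidean
distance to its eight neighbors in $(u',v')$, and the achromatic difference
the mean $|\Delta L|$; the one-pixel border, where the 8-neighborhood is
undefined, is excluded rather than padded. Per-image means of the two maps
feed a per-corpus Pearson correlation (two-sided t-approximation p-value by
default; a one-sided alternative can be requested, since published analyses
of this statistic are not always explicit about sidedness).

## The synthetic generator as a test instrument

`generate_still_life()` authors pixels directly in DKL and maps them to
sRGB through the *inverse* of the configured transform, so the chromatic
ground truth is exact by construction rather than estimated. The scene
model is minimal but hits every statistical feature the pipeline consumes:

* 3–8 elliptical "fruit" blobs with hues drawn from 15°–75° inside the warm
  quadrant, on a background at 215° in the cool quadrant Q3 — reproducing
  the Q1/Q3 occupancy bias typical of natural scenes and still lifes;
* background radial contrast `base_saturation = 0.3`, a mid-range
  saturation that keeps even a doubled warm gain fully inside the display
  gamut (clipping is reported and stays at zero at defaults);
* a dark-biased luminance mixture (60% of background pixels from a dark
  component) plus bright fruit, emulating the dark-background bias of
  still-life imagery;
* smooth seeded textures: hue jitter applied *orthogonally to the radius*
  (so chromatic texture never changes radial contrast) and independent
  luminance noise — giving separate dials for the chromatic and achromatic
  local-difference channels.

The warm effect itself, `warm_saturation_gain` $g$, multiplies the **L/M
component** of fruit chroma: $(g\,r_0\cos h,\; r_0\sin h)$. The isoluminant
radius $r_0\sqrt{g^2\cos^2 h + \sin^2 h}$ is strictly increasing in $g$ and
equals the background's at $g=1$, so the null case is exact; and because
the S coordinate is untouched, the S-vs-achromatic control plane is
invariant to $g$ by construction. A purely radial boost would scale the S
coordinate too and leak the injected effect into the blue-quadrant control,
contradicting the empirical pattern the generator exists to emulate — a
warm-specific saturation excess with silent cool-plane statistics. The
condition defaults ($g = 1.5$ painting-like, $g = 1.15$ photo-like, all
other parameters shared) were fixed once as the package's study conditions.

What the generator does **not** emulate: photorealistic shapes or shading,
pigment or period effects, and — importantly for the local-difference
module — the natural coupling of luminance and chromaticity edges that
makes the two difference channels positively correlated in photographs of
real scenes. In the generator the textures are independent by design, and
across images the two statistics are coupled only through scene
composition (more fruit area means more chromatic edges and fewer
dark-background luminance edges), which can produce a *negative*
across-image correlation. Passing tests therefore certify the measurement
chain and the warm-effect recovery, not any claim about correlations in
real corpora.

## Numerical choices and degenerate inputs

* Rounding of contrast levels is half-away-from-zero at 4 decimals; the
  level count of the default grid (1,464) pins the convention against an
  independently written enumeration in the tests.
* Bootstrap order statistics are $\max(1,\lfloor n(1-\alpha)/2\rfloor)$ and
  $n - \lfloor n(1-\alpha)/2\rfloor$ (25/975 at $n=1000$, $\alpha=0.05$),
  with an epsilon guard against floating-point residue in the product.
* Out-of-range DKL pixels are excluded from the grid but counted and
  carried through normalization ($\sum h + \text{oor fraction} = 1$).
* Chromograms average sRGB-encoded values (what a renderer displays), not
  linear light; the chromogram is a visualization, so display-space
  averaging is the honest default and is configurable in principle.
* Empty images, empty masks, mixed-plane averages, non-invertible matrices,
  sub-3×3 images for the 8-neighborhood, and zero-variance correlations are
  all rejected with specific errors rather than propagating NaN.
* Unreadable files in a corpus are skipped with a warning and counted in
  the report; an empty corpus is fatal.

## Problem sizes used in the test-suite simulations

The validation suite runs the full chain on 64×64 synthetic images: null
calibration of the warm-excess difference over 100 replicate corpus pairs
(8 images each), effect recovery at $g=1.5$ vs $g=1.15$ over 100 replicate
pairs of 40-image corpora (with the blue control required to show no
systematic ordering), and bootstrap coverage over 200 replicates of 200
Gaussian curves at 60 levels. These sizes give the simulations stable
verdicts (binomial and Monte-Carlo standard errors small relative to the
margins being tested) while keeping the whole suite quick to run on a
laptop.

## Known limitations

* The DKL transform is display-referred: inputs must be (approximately)
  sRGB; ICC profiles and spectral data are out of scope.
* The warm/cool quadrant dichotomy is a proxy for object/background, not a
  segmentation; masked histograms (`masked_histogram()`) are provided for
  region-of-interest analyses where real masks exist.
* Percentile bootstrap bands undercover slightly for very small corpora
  (the usual $O(1/N)$ effect); with corpus sizes in the dozens this is
  negligible relative to the visual comparisons the bands support.
* The acceptance-style statistics are scale-free but not unitless in any
  perceptual sense; they are comparative devices, not absolute saturation
  measurements.
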