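---
title: "Methods: image-based seedling phenotyping and QTL interval mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based seedling phenotyping and QTL interval mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscan)
```

phenoscan is a desk-scale pipeline for early-vigor phenotyping of
seedlings from RGB images and for mapping quantitative trait loci (QTL)
of the extracted traits on a recombinant inbred line (RIL) population.
This vignette documents the statistical model behind each stage, the
parameter defaults and their rationale, what the synthetic data
generators do and do not emulate, and the numerical choices that matter
for reproducibility.

## 1. Color spaces and channel rescaling

Plant tissue is separated from soil/background color by thresholding
three derived channels rather than raw RGB.

**HSI.** `rgb_to_hsi()` uses the geometric (arccos) hue-saturation-
intensity model: intensity is the channel mean, saturation is
$1 - 3\min(R,G,B)/(R+G+B)$, and hue is the angle of the color around
the gray axis with red at 0° and colors with $B > G$ mapped to
(180°, 360°). Hue is undefined for achromatic pixels ($R=G=B$); these
carry hue 0 together with an explicit `achromatic` flag (saturation
below $10^{-6}$) so that thresholding on dense arrays stays well
defined and an achromatic pixel can never pass a hue window by
accident.

**CIELAB.** `rgb_to_lab()` interprets pixels as 8-bit sRGB and converts
through linear light and CIE XYZ to CIELAB under the D65 reference
white (2° observer). The linear-light matrix is derived in closed form
from the sRGB primary chromaticities and the D65 white point rather
than hard-coded, so the matrix and the Lab white normalization share
one set of defining constants. The unit tests cross-check the full
chain against two independent implementations (a frozen scalar oracle
and the farver package).

**Rescaling.** The three classification channels are put on a common
0-255 scale:

$$Y_{a^*} = \frac{a^* + 100}{200} \times 255, \qquad
  Y_{b^*} = \frac{b^* + 100}{200} \times 255, \qquad
  Y_H = \frac{H}{360} \times 255.$$

$a^*$ and $b^*$ are clipped to $[-100, 100]$ first (values outside
that range occur only for extreme saturated colors) so the output
honors the 0-255 contract; hue outside $[0, 360]$ is an error because
it indicates a bug upstream rather than a legitimate color.

## 2. Segmentation

`segment_plant()` chains five stages, all operating on logical
matrices:

1. **Channel threshold** (`channel_threshold_mask()`): a pixel is
   plant if its hue lies in `hue_window` **and** it is green-ish in
   Lab terms (`y_a <= a_green_max` **or** `y_b >= b_yellow_min`).
   The AND-of-OR combination is a documented design choice: hue is the
   primary discriminator, and the Lab condition rejects hue-window
   impostors that are neither green on the a* axis nor yellow on the
   b* axis. Defaults: `hue_window = c(35, 120)` (yellow-green to
   green), `a_green_max = 120` (scaled a* below mid-scale, i.e.
   $a^* < -5.9$), `b_yellow_min = 135` (scaled b* above mid-scale,
   $b^* > 5.9$). Achromatic pixels never pass.
2. **Median denoise** (`median_denoise()`, radius 1): majority filter
   over the $(2r+1)^2$ window with replicate padding at the borders.
   Note that a majority filter shaves the four corners of a solid
   rectangle (a corner has only 4 of 9 set neighbors); this is the
   mathematically correct behavior of the operator, verified against a
   brute-force oracle, not a boundary bug.
3. **Morphological opening** (`morphological_refine()`): erosion then
   dilation with a 3x3 square element, one iteration. Erosion/dilation
   treat outside-image pixels as background. Opening is idempotent,
   which the tests verify.
4. **Hole filling** (`fill_holes()`): background reachability from the
   image border under 4-connectivity; unreachable background becomes
   foreground. Implemented as alternating column/row run propagation to
   a fixed point, which is equivalent to (and tested against) a
   breadth-first flood fill.
5. **Small-component removal** (`remove_small_components()`):
   8-connected components below `min_component_area = 20` px are
   dropped. At the default scene scale a seedling blade is hundreds of
   pixels, so 20 px removes salt-noise clusters without touching
   plausible plants.

## 3. Trait extraction

`projected_height()` is the inclusive vertical extent of the mask in
pixel rows (optionally measured from a fixed `soil_row`), and
`pixel_area()` is the foreground count. `calibrate()` converts px to mm
with a scalar `mm_per_px`. The trait vocabulary is closed
(`PH_px`, `PH_mm`, `AREA_px`, `SL_mm`, `FW_g`); records are validated
for vocabulary membership, non-negative values, and unique
(line, replicate, trait) keys at every I/O boundary.

## 4. Trait statistics

For a one-way fixed-effects line model the least-square mean of a line
equals its arithmetic mean, balanced or not; `least_square_means()`
exploits that and the tests verify it against an explicit
normal-equations solve on unbalanced layouts.
`pearson_correlation()` uses the definitional covariance formula with
the $t$-transform p-value. `residual_variance_ftest()` compares the
residual mean squares of two traits with a two-sided p-value
$2\min\{P(F \le f), P(F \ge f)\}$; both tails are evaluated in their own
orientation so that swapping the traits gives a bitwise-identical
p-value. Because traits sit on different measurement scales, residuals
are by default formed after z-scaling by the trait's grand SD
(`one_way_residuals(standardize = TRUE)`), making residual variances
comparable across traits; this standardization is a documented choice,
not an inference about any particular historical analysis.

## 5. QTL interval mapping

**Genotype model.** RILs are treated as fully inbred: two homozygote
classes, heterozygote calls recoded to missing with a warning. Map
distance converts to recombination fraction by Haldane
($r = (1 - e^{-2d/100})/2$, no interference) and to the observable RIL
recombination fraction by the expansion $R = 2r/(1+2r)$.

**Conditional probabilities.** `conditional_genotype_probs()` computes
$P(\text{AA at } p \mid \text{flanking markers})$ on a grid that
includes every marker. For a position with informative markers on both
sides the probability is normalized over the intermediate genotype:
$$P(AA \mid L, R) =
\frac{t_{L\to A}\, t_{A\to R}}{t_{L\to A}\, t_{A\to R} + t_{L\to B}\, t_{B\to R}},$$
with $t$ the RIL-expanded transmission probabilities. This Markov-chain
normalization (the standard interval-mapping treatment) is used instead
of a closed-form flank-to-flank denominator because the RIL-expanded
$R$ is not additive-consistent: only the normalized form makes the two
class probabilities sum to exactly 1, which is an invariant the package
asserts. Positions with one informative flank use the single-marker
conditional; positions with none fall back to 1/2.

**Scan.** `interval_mapping_scan()` performs Haley-Knott regression of
line means on $P(AA)$; because the regression has a single predictor,
$\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{1}{1-r^2}$, computed
vectorized across all positions. The residual sum of squares is floored
at $10^{-12} \cdot \mathrm{RSS}_0$ so a perfect fit yields a large
finite LOD rather than infinity.

**Threshold.** `permutation_threshold()` permutes line means, rescans
(as one matrix cross-product for all permutations), records genome-wide
maximum LODs and returns their empirical $(1-\alpha)$ quantile (type-7
interpolation). The seed is a required argument; thresholds are
bit-reproducible.

**Peak calling.** `call_qtl_peaks()` reports, per chromosome, local
maxima above the threshold with a LOD-drop support interval
(`drop_lod = 1.5`). A called peak claims its support interval, its
contiguous above-threshold run, and everything within
`min_sep_cM = 30`: at populations of a few hundred lines, linked QTL
closer than ~30 cM are not statistically separable, so closer secondary
maxima are shoulders of one signal. The documented trade-off is that
two genuinely linked QTL under 30 cM apart merge into one call.

## 6. Synthetic data: what is and is not emulated

`generate_seedling_image()` renders 1-5 linear blades with small random
slopes growing up from a base row, green with per-pixel jitter, on a
brown soil-like background with optional green salt noise. The ground
truth mask is the *hole-filled* blade silhouette: crossing blades can
enclose a background pocket, and since the segmentation contract treats
enclosed holes as plant, the benchmark truth must too (the rendered
image still paints only blade pixels green). The generator emulates
exactly what the pipeline needs to be falsifiable — known silhouette,
tip row, and area — and deliberately does not emulate lens distortion,
shading, leaf curvature, occlusion by hardware, or soil texture
variation beyond uniform jitter.

`simulate_ril_population()` draws RIL genotypes chromosome-by-
chromosome as a Markov chain with RIL-expanded transition
probabilities, plants QTL as loci simulated jointly with the markers
and then hidden, and scales replicate noise so that the line-mean
heritability equals the requested $h^2$. `generate_study_fixture()`
combines both: 162 lines x 8 replicates genotyped at 224 markers on 12
chromosomes, a height-like trait with QTL on chromosomes 1, 4 and 12, a
fresh-weight-like trait sharing the chromosome-1 locus, genetic
correlation planted at 0.66, and a subset of lines rendered as scenes
whose blade lengths encode the genetic height values. The population
size, marker count, and chromosome-1/4/12 architecture are the
package's own fixture choices, sized so the full study runs in seconds.

## 7. Numerical and reproducibility choices

- All simulators take an explicit integer seed; `run_study()` derives
  its internal seeds (fixture, thresholds) from the one it is given,
  and its CSV outputs are byte-identical across runs.
- CSV artifacts carry `#` header lines with the package version, seed,
  and a digest of the configuration, so any table can be traced to the
  exact settings that produced it.
- Numeric CSV fields are serialized at 15 significant digits, which
  round-trips doubles through text losslessly for this value range.
- Quantile type 7 (R's default) is pinned for permutation thresholds;
  changing the type changes thresholds at small permutation counts.
- The morphology, hole-filling and labeling code is vectorized base R
  (shift/rowsum operations), fast enough that a 512x512 scene segments
  in well under a second without compiled dependencies.

## 8. Limitations

- Single-QTL regression scan: no composite interval mapping, no
  cofactors, no epistasis; closely linked QTL merge (see `min_sep_cM`).
- The F test compares residual variances of z-scaled traits; it is a
  precision comparison, not a variance-components analysis.
- The scene generator's plants are piecewise-linear blades; real canopy
  self-occlusion and curvature are out of scope.
- Only two-class (RIL) populations are supported; F2/backcross designs
  would need a three-class genotype model.
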