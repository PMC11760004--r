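---
title: "Quantifying marbling fineness: model, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marbling fineness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marblefine)
```

## The problem

Marbling — intramuscular fat visible as white flecks on a muscle
cross-section — is graded visually by its *amount* (e.g. the Korean BMS
scale, 1–9). But consumers also discriminate by *fineness*: many small,
evenly spread flecks versus few large streaks at the same total fat
content. `marblefine` measures fineness objectively from a photograph of
the sirloin cross-section plus a region-of-interest (ROI) mask that
delimits the muscle (the ROI is an input: the muscle boundary is drawn or
supplied externally, not detected automatically).

## The pipeline and its assumptions

**Segmentation.** Fat is brighter than lean muscle, so a per-image global
threshold on luminance separates the two. We use Otsu's criterion — the
threshold `t` maximizing the between-class variance of the 256-bin
intensity histogram — with three conventions:

* The histogram is built from **ROI pixels only**. A removed (black)
  background would otherwise form a spurious third mode and drag the
  threshold down.
* Luminance is the ITU-R 601 combination `0.299 R + 0.587 G + 0.114 B`,
  rounded; inputs of higher bit depth are rescaled to 8-bit first. The
  choice of weights is essentially immaterial for white-on-red contrast
  but is fixed for reproducibility.
* Ties between maximizing thresholds (exact ties occur across zero-count
  histogram gaps) are broken toward the **smallest** threshold.

The assumption to be aware of is *even illumination*: a global histogram
threshold cannot compensate brightness gradients across the cut surface.
Uneven lighting is a known failure mode of this class of methods and is out
of scope here; `otsu_threshold()` has a method hook should alternative
thresholding algorithms be added.

**Particle morphometry.** Connected components of the fat mask are the
marbling particles. Defaults and conventions:

* **8-connectivity** by default (a thin diagonal streak stays one fleck);
  4-connectivity is available. Component ids follow row-major first
  encounter, and the particle table is sorted ascending by area with ties
  broken by id, so all downstream ranks are deterministic.
* **Perimeter** is the count of exposed unit pixel edges (a single pixel
  has perimeter 4, a 2×2 block 8). It is simple, integer-valued and exact
  under pixel replication (doubling resolution doubles it), at the price of
  overestimating smooth-boundary length; since every image in a study is
  measured with the same estimator, comparisons are unaffected.
* The **half-cumulation statistics**: `A50` is the area of the particle at
  which the ascending cumulative area first reaches 50 % of `A_total`
  (smallest rank `k` with cumulative fraction ≥ 0.5 — an exact-half
  condition is generically unattainable with integer areas, and `≥` is its
  natural closure). `P50` is defined identically on the perimeter-sorted
  cumulative perimeter. `F4` counts the particles strictly before that
  point, i.e. the number of smallest particles whose cumulative area
  fraction stays below 0.5.
* No minimum particle size is imposed by default (`min_area = 1`); a
  filter is available for noisy imagery, but note that area conservation
  against the mask holds only at the default.

**The F7 index.** The fineness signal proper: split the image into tiles,
measure each tile's fat-area ratio, and summarize their dispersion.

1. The **ROI bounding box** is split into `step × step` tiles with integer
   boundaries `floor(k · extent / step)`, `k = 0..step` (half-open).
   Anchoring tiles to the bounding box rather than the full image frame
   makes the step size meaningful relative to the muscle extent and images
   of different sizes comparable.
2. A tile enters the statistic when at least `min_coverage` (default 0.5)
   of its pixels lie inside the ROI. For included tiles the ratio is
   `x_i = fat pixels / ROI pixels` in the tile — border tiles are
   normalized by their muscle portion, so a half-covered rim tile full of
   fat counts like an interior tile full of fat, not like a half-empty one.
3. `F7 = sd(x_i)`, the sample standard deviation (denominator `n − 1`).

Fine marbling equalizes the tile ratios (F7 low); coarse marbling
concentrates fat in few tiles (F7 high). F7 is dimensionless, zero iff all
ratios are equal, and bounded by `0.5·sqrt(n/(n−1))` for ratios in [0, 1].

**Tunable parameters.**

| parameter | default | unit | role |
|---|---|---|---|
| `step` | 70 | tiles/axis | tile resolution of F7; the package's standard operating point. The best-separating step is dataset-dependent — re-derive it for new imagery with `step_size_sweep()` |
| `min_coverage` | 0.5 | fraction | ROI coverage required to include a tile |
| `connectivity` | 8 | — | particle adjacency rule |
| `min_area` | 1 | px | particle noise filter (off) |
| `pixels_per_cm` | none | px/cm | scale calibration; needed only by the Kuchida index, which has physical (cm²) size bounds — there is deliberately no default |

**Companion indices.** F1a–F6 and F8 are simpler candidates computed
alongside F7 for comparison (counts, totals, half-cumulation values and
ratios; `F5 = avg(p²/a)` is a shape-compactness average; `F8 = F2b/F7`).
The **Kuchida index** — particles of 0.01–0.5 cm² per cm² of loin-eye — is
the classical fineness measure from the Wagyu literature; it counts small
flecks directly, so it should (and in our synthetic validation does)
correlate *negatively* with F7.

## Group statistics

* **Welch t test** (unequal variances, two-sided) for fine-vs-coarse
  contrasts; the pooled-variance Student test is available via
  `var_equal = TRUE`. Degenerate inputs are resolved explicitly: both
  variances zero with equal means is an exact tie (p = 1); with distinct
  means the statistic diverges and p = 0 is reported with a `degenerate`
  flag rather than an error.
* **One-way ANOVA** for three-group comparisons (`F = MSB/MSW`,
  df `(k−1, N−k)`).
* **Bootstrap**: nonparametric percentile 95 % CI of the group mean,
  B = 1000 by default, seeded and reproducible; it accompanies point
  estimates without altering them.
* **Step sweep**: F7 at every step in 5–95 (increment 5, 19 grids), Welch
  fine-vs-coarse p per step, optimum = argmin p with ties to the smaller
  (cheaper) grid.
* No multiple-testing correction is applied across indices or grades; the
  package reports raw p values and leaves adjustment to the analyst.

## The synthetic generator

Real graded cross-section panels are proprietary, so validation runs on
synthetic images with known truth. The generator is a **Boolean model**:
elliptical fat blobs (radius ~ truncated normal, mild random elongation up
to `1 + shape_irregularity`, random orientation) are placed at uniform ROI
positions until the fat fraction inside the ROI first reaches the target;
the final blob's overshoot is trimmed back pixel-by-pixel, so the realized
fraction equals the target to within rounding (far inside the documented
±0.02 tolerance). Rendering draws fat at luminance 200, lean at 120 with a
mild red tint (luminance preserved), background dark, and adds per-channel
Gaussian noise with sd 8 — an 80-level contrast at which Otsu recovery of
the truth mask is essentially exact (the suite requires ≥ 99 % ROI-pixel
agreement). One integer seed fully determines an image; panel seeds are
`base_seed + index`.

The three fineness presets share a fat fraction of 0.35 on 560 × 560 px
images with a 400 × 480 px elliptical ROI and differ **only** in blob
radius: fine 2 px, medium 6 px, coarse 12 px (sd = mean/4). Matching the
fraction is the point of the design — total fat amount is the confound a
fineness index must ignore — and the suite asserts that mean total fat
area differs by < 5 % between fine and coarse panels while F7 still
separates them. The ROI bounding box (≥ 400 px per axis) keeps every step
size in the 5–95 sweep valid. For the Kuchida correlation panel we
calibrate 30 px/cm at full size (a ≈ 19 cm field of view, realistic for a
sirloin cross-section) and 15 px/cm on half-size images.

What the generator does **not** emulate: illumination gradients, camera
optics, specular highlights, connective tissue, anisotropic streak shapes
beyond mild elongation, or the fat/lean texture of real muscle. Passing
tests therefore demonstrate the *mechanics* of the method — segmentation
accuracy under known contrast and noise, index behaviour under controlled
particle-size manipulation at matched fat amount, calibration of the test
statistics — not field performance on real carcass photographs.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
exhaustive between-class-variance search for Otsu (200 random histograms);
hand enumeration and brute-force cumulation for particle statistics (500
random multisets; 100 random masks for exact area conservation);
closed-form tile patterns for F7 (agreement to 1e-12); EBImage's labeller
as a cross-check of the 4-connectivity path. System-level checks use a
60-image three-group panel (20 per group, presets above) analysed end to
end at step 70 — mean F7 must order coarse > medium > fine with a
significant Welch fine-vs-coarse contrast — plus a null calibration (200
replicate two-group panels of 6 + 6 images at 160 × 160 px from an
*identical* generator, rejection rate required to sit within 2–8 % at
α = 0.05), a five-radius panel for the sign and strength of the F7–Kuchida
correlation (r < −0.5), and bit-reproducibility of the 19-step sweep.
These sizes keep the full suite under a couple of minutes on one CPU while
leaving each statistical assertion comfortable margins.

## Numerical conventions and degenerate inputs

* All package errors are classed conditions (`mf_error_*`), so callers can
  distinguish a degenerate histogram (constant ROI), an empty marbling
  mask, an invalid step size (bounding box smaller than the step), an
  excluded-tile grid, insufficient samples, or a missing scale
  calibration, and the pipeline can skip-and-log per image instead of
  aborting a panel.
* F8 is undefined at F7 = 0 and raises `mf_error_undefined_ratio`
  (`compute_all()` reports `NA` instead, since a panel may legitimately
  contain a perfectly uniform mask).
* Determinism contract: every result is a pure function of (inputs,
  configuration, seed). Generation and bootstrap use an isolated RNG state
  (`Mersenne-Twister`, rejection sampling) that never disturbs the
  caller's stream; reruns of the pipeline produce byte-identical CSVs.

## Limitations

* Global thresholding assumes even illumination and a bimodal ROI
  histogram; very lean (BMS ≤ 2) or glare-affected images may segment
  poorly.
* The ROI must be supplied; there is no automatic muscle-boundary
  detection.
* The perimeter estimator is digital (edge counting), not a length
  estimate of the smooth boundary; F3/F5/F6 values are comparable within
  the convention only.
* Synthetic validation bounds what can be claimed about real images (see
  above); the defaults (step 70, coverage 0.5) travel to other image
  scales only insofar as the ROI bounding box is comparable, which is why
  the sweep tooling ships with the package.
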