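# marblefine

Quantifying **marbling fineness** from beef sirloin cross-section images.

Two cuts of beef can carry the same total amount of intramuscular fat (IMF)
yet look — and eat — very differently: *fine* marbling spreads many small fat
flecks evenly over the cut surface, while *coarse* marbling concentrates the
same fat into a few large streaks. Visual marbling scores (e.g. the Korean
BMS 1–9 scale) grade the *amount* of fat, not its *distribution*, so fineness
needs its own instrument. This package is that instrument: it segments the
fat flecks from an RGB cross-section photograph and computes a family of
fineness indices, centrally the tile-grid heterogeneity index **F7**.

## The method

Given an image and a region-of-interest (ROI) mask delimiting the muscle:

1. **Segmentation.** The image is converted to luminance and thresholded by
   Otsu's method, with the histogram built from ROI pixels only; the bright
   class is the fat (marbling) mask.
2. **Particle morphometry.** Connected fat components (8-connectivity by
   default) give per-particle areas `a_i` and perimeters `p_i`, their totals
   `A_total = Σ a_i`, `P_total = Σ p_i`, and the half-cumulation statistics
   `A50` / `P50`: the area (perimeter) of the particle at which the ascending
   cumulative area (perimeter) first reaches 50 % of the total.
3. **Indices.** F1a (particle count), F1b (`A_total`), F2a/F2b (`A50`,
   `A50/A_total`), F3a/F3b (`P50`, `P50/P_total`), F4 (particles below the
   half-cumulation point), F5 (`avg(p² / a)`), F6 (`A50 · P50`), F8
   (`F2b / F7`), the Kuchida fineness index (particles of 0.01–0.5 cm² per
   cm² of loin-eye), and

   **F7** — partition the ROI bounding box into `step × step` tiles
   (default `step = 70`), let `x_i` be the fat-area ratio of tile `i`, and
   take the sample standard deviation

   ```
   F7 = sqrt( Σ (x_i − x̄)² / (n − 1) )
   ```

   Evenly distributed fine marbling makes the tile ratios nearly equal
   (low F7); coarse streaks concentrate fat in few tiles (high F7).
   **Lower F7 = finer marbling.**

Group tooling compares fine/medium/coarse panels (Welch t test, one-way
ANOVA, bootstrap CIs) and sweeps the step size to find the resolution that
best separates fine from coarse. A seeded synthetic generator (a Boolean
model of deformed disks at matched fat fraction) produces labelled test
panels with known truth masks, so the entire pipeline is verifiable without
proprietary graded images.

## Worked example

```r
library(marblefine)
cfg <- mf_config(step = 70, pixels_per_cm = 30)
for (lbl in c("fine", "coarse")) {
  img <- generate_image(fineness_preset(lbl, seed = 7))
  iv  <- compute_all(img$image, img$roi, cfg, image_id = paste0(lbl, "_demo"))
  print(as.data.frame(iv)[, c("image_id", "F1a", "F1b", "F2b", "F7", "F8",
                              "kuchida", "threshold_used")], digits = 4)
}
#>    image_id  F1a   F1b      F2b     F7       F8 kuchida threshold_used
#> 1 fine_demo 1217 52787 0.001781 0.2275 0.007827   6.057            142
#>      image_id F1a   F1b     F2b     F7    F8 kuchida threshold_used
#> 1 coarse_demo  52 52787 0.02658 0.4287 0.062 0.08354            147
```

Both images hold exactly the same fat area (F1b = 52 787 px — the matched
fraction of 0.35) yet the fine image scatters it over 1 217 particles and
scores F7 = 0.23, while the coarse image has 52 large flecks and
F7 = 0.43: the index isolates distribution from amount. The Kuchida index
(small-particle density) moves the opposite way, as it should.

From a shell, the same pipeline is available as subcommands:

```sh
Rscript exec/marblefine simulate --n 20 --seed 42 --out panel/
Rscript exec/marblefine run --images panel/images --rois panel/rois \
    --manifest panel/manifest.csv --out results/ --step 70 --pixels-per-cm 30
Rscript exec/marblefine compare --indices results/indices.csv --index F7 \
    --out comparisons.csv
```

`run` writes per-image masks (with the Otsu threshold in a JSON sidecar),
particle tables, `indices.csv`, `comparisons.csv` and a run log; reruns with
identical inputs are byte-identical.

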