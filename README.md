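# gridpeaks

Superpixel segmentation by **density-peak clustering of grid feature
points** in CIELAB color space, with Boundary Recall / Achievable
Segmentation Accuracy evaluation. The package targets bioimage (and
general image) preprocessing pipelines that want *few, meaningful*
superpixels: unlike SLIC-style methods that tile homogeneous regions
with redundant segments, density-peak selection merges smoothly
connected regions into single superpixels while keeping boundaries on
the salient contours.

## Method

1. **Lab conversion.** The 8-bit RGB image is mapped to CIELAB through a
   fixed RGB→XYZ matrix (applied to channels scaled to [0, 1]) and the
   CIE transform with white point (Xn, Yn, Zn) = (0.9505, 1, 1.089).
   Optional sRGB linearization is available (`srgb = TRUE`).
2. **Grid feature points.** One point per R×R cell at the cell center;
   its feature (L̄, ā, b̄) is the block mean over the cell — an R×R mean
   filter that suppresses secondary texture.
3. **Color-gated density.** For each point *p*,
   ρ(p) = #{ q : ‖x_q − x_p‖ ≤ K and ‖f_q − f_p‖² ≤ ψ },
   with spatial radius K (default 1.3R, spanning the four axial grid
   neighbors) and squared-Lab color gate ψ (default 13).
4. **Density peaks.** Points are ranked by ρ (descending); each point's
   δ is the distance to its nearest higher-ranked point. After min–max
   normalization, centers are the points with ρ′·δ′ > a (curve /
   λ-threshold rules, default a = 0.005) or the top-M by λ = ρ′δ′ when a
   fixed superpixel count M is required. The densest point is always a
   center.
5. **Assignment.** Every remaining point follows its
   nearest-denser-neighbor link until a center is reached (single-pass,
   chains always terminate). Cluster labels are lifted to pixels by
   nearest feature point, giving the superpixel label map.

Evaluation: **BR** = fraction of ground-truth boundary pixels within
Chebyshev distance ε (default 2) of a predicted boundary pixel; **ASA**
= Σ_s max_g |s ∩ g| / #pixels over superpixels s and ground-truth
regions g.

## Worked example

```r
library(gridpeaks)
scene <- make_disk(240, 320, noise_sd = 2, seed = 2)   # known ground truth
seg <- segment_image(scene$rgb, grid_params(R = 8, strategy = "topM", M = 2))
print(seg)
#> gp_segmentation: 2 superpixels, 1200 feature points, R = 8
met <- segmentation_metrics(seg$map, quantize_labels(scene$gt, 8))
sprintf("BR = %.3f, ASA = %.3f", met$br, met$asa)
#> "BR = 0.715, ASA = 0.988"
```

The 240×320 image yields 30×40 = 1200 feature points at R = 8. The
requested two superpixels recover the disk against its background;
ASA 0.988 means 98.8 % of pixels could be labeled correctly by majority
vote over superpixels. BR = 0.715 at ε = 2 reflects a real limitation of
the chain assignment: grid cells straddling the curved disk boundary
attach to an arbitrary side (the parent links are purely spatial), so
the superpixel boundary locally deviates by up to one grid cell from
the true interface — see the methods vignette for the analysis. On
grid-aligned boundaries (e.g. `make_two_region()`), BR = 1 and ASA = 1
exactly.

## Command line

```sh
Rscript inst/cli/gridpeaks.R segment --input img.png --out outdir \
        [--R 8] [--psi 13] [--strategy curve|lambda|topM] [--M n] \
        [--resize 320x240] [--enforce-connectivity]
Rscript inst/cli/gridpeaks.R eval --pred labels.csv --gt gt.csv [--epsilon 2]
Rscript inst/cli/gridpeaks.R fixtures --out DIR --seed 0
```

`segment` writes `labels.csv` (+ two-byte-encoded `labels.png`),
boundary and mean-fill renderings, `density.csv` (ρ, δ, λ per feature
point) and `summary.csv`. Runs are deterministic: identical input and
parameters give byte-identical outputs.

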