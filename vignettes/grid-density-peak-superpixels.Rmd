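---
title: "Grid-point density-peak superpixels: model, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-point density-peak superpixels: model, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpeaks)
```

## The model

Superpixel methods that tile the image plane uniformly (SLIC, LSC, …)
produce many redundant segments inside smoothly connected homogeneous
regions. `gridpeaks` instead treats superpixel extraction as a
*clustering of a sparse grid of feature points* by density peaks, so
the number and size of superpixels adapt to local color structure: one
big superpixel per homogeneous region, small ones only where color
changes.

The pipeline has five stages.

**1. Color space.** RGB is converted to CIELAB through the fixed matrix

$$\begin{pmatrix}X\\Y\\Z\end{pmatrix} =
\begin{pmatrix}
0.4124 & 0.3576 & 0.1805\\
0.2126 & 0.7152 & 0.0722\\
0.0193 & 0.1192 & 0.9505
\end{pmatrix}
\begin{pmatrix}R\\G\\B\end{pmatrix},\qquad R,G,B\in[0,1],$$

followed by $L = 116 f(Y/Y_n) - 16$, $a = 500[f(X/X_n)-f(Y/Y_n)]$,
$b = 200[f(Y/Y_n)-f(Z/Z_n)]$ with white point
$(X_n, Y_n, Z_n) = (0.9505, 1, 1.089)$ and the CIE piecewise
$f(t) = t^{1/3}$ for $t > (6/29)^3$, else
$t/(3(6/29)^2) + 4/29$. Each matrix row sums to its white-point
component, so pure white maps to $(100, 0, 0)$ and the gray axis to
$a = b = 0$ — both are test anchors.

*Gamma.* By default the matrix is applied to linearly scaled channel
values with **no** sRGB expansion. This is a deliberate design choice:
the method's color gate was calibrated in that convention. A
color-accurate mode (`srgb = TRUE`) linearizes first; both modes are
exactly invertible through `lab_to_rgb()`.

**2. Grid feature points.** One feature point per $R\times R$ cell,
placed at the cell center (row $R(r-1) + \lfloor R/2\rfloor + 1$), with
feature $(\bar L,\bar a,\bar b)$ the arithmetic block mean over the
cell. This gives exactly $\lfloor H/R\rfloor\cdot\lfloor W/R\rfloor$
points — e.g. 1200 on a 240×320 image at $R=8$ — and acts as an
$R\times R$ mean filter suppressing fine texture. A literal corner
placement ($h = Rr$ from the origin) would both overshoot the stated
point count and push half of the boundary windows outside the image,
so the cell-center convention is used and documented here rather than
hidden. Remainder strips when $R \nmid H$ get no point; they join their
nearest cell at the label-map stage.

**3. Color-gated density.** For point $p$,

$$\rho(p) = \#\{\,q : \lVert x_q - x_p\rVert \le K \ \text{and}\
(\bar L_q-\bar L_p)^2 + (\bar a_q-\bar a_p)^2 + (\bar b_q-\bar b_p)^2
\le \psi\,\},$$

including $p$ itself, so $\rho \ge 1$ always. Two conventions needed
fixing:

* *Spatial gate.* Comparing the **squared** distance against $K$ (a
  literal reading of the source equations) makes $K = 1.3R$ capture no
  neighbor at all; the Euclidean distance is used, under which $1.3R$
  spans exactly the four axial grid neighbors ($\rho = 5$ in a uniform
  interior — a frozen test value) but not the diagonals at $R\sqrt2$.
  The literal form remains available as `strict_literal = TRUE`.
* *Color gate.* Applied to the **squared** Lab distance versus $\psi$,
  as printed: $\psi = 13$ therefore means a Lab radius of about 3.6.
  `squared_color = FALSE` switches to the unsquared convention.

Because the points form a regular lattice, neighbor search enumerates
only the $O(1)$ grid offsets within radius $K$, giving $O(Nk)$ density
computation; the $O(N^2)$ scan exists only as a test oracle.

**4. Center selection.** Points are ranked by descending $\rho$ (ties:
ascending raster index). $\delta_m$ is the distance to the nearest
higher-ranked point; the top-ranked point takes the maximum of the
other $\delta$. After min–max normalization of $\rho$ and $\delta$ to
$[0,1]$ (all-equal inputs normalize to all zeros), centers are chosen
by one of three rules:

| rule | selects | default |
|------|---------|---------|
| `curve` | $\rho'\delta' > a$ (above the hyperbola $\delta' = a/\rho'$) | $a = 0.005$ |
| `lambda` | $\lambda = \rho'\delta' > \lambda_0$ | $\lambda_0 = 0.005$ |
| `topM` | $M$ largest $\lambda$ (ties: raster index) | — |

The separator was printed upstream as $\delta' = a\rho'$ but described
as an inverse function with centers "above the curve"; only
$\delta' = a/\rho'$ divides the plane that way, so the inverse form is
implemented — under which `curve` and `lambda` coincide. Both entry
points are kept since they are presented as distinct rules. Threshold
equality is excluded (strict `>`), and the rank-0 point is always
forced into the center set, even in the degenerate all-zero-$\lambda$
case.

**5. Assignment and label map.** Each non-center point follows its
*parent* — the nearest point of strictly smaller rank — transitively to
a center (parents strictly decrease rank, so chains terminate; the
rank-0 point is a center by construction). Pixels take the label of
their nearest feature point (ties to the lower raster index), making
each superpixel a union of grid cells.

*Tie-break choice (genuinely open design point).* When several
earlier-ranked points are exactly equidistant from a point — the common
case on the density plateaus of homogeneous regions, where whole
regions share one integer $\rho$ — the implemented rule takes the
**earliest rank** (the densest candidate, with raster index breaking
only density ties). The alternative, "lowest raster index among
equidistant candidates", was tried and rejected: on a noise-free
two-region image it attaches the first boundary-column point to its
lower-index neighbor *across* the color boundary, leaking an entire
column of points into the wrong cluster. The earliest-rank rule is
equally deterministic and keeps boundary points attached to their own
region's interior.

## Parameters

| parameter | meaning | default | why |
|-----------|---------|---------|-----|
| `R` (px) | grid interval; sets feature-point count $\lfloor H/R\rfloor \lfloor W/R\rfloor$ and minimum boundary resolution | 8 | quality/efficiency compromise of the upstream experiments; 4–10 useful |
| `K` (px) | spatial density radius | $1.3R$ | spans axial neighbors only |
| `psi` | squared-Lab color gate | 13 | ≈ 3.6 Lab units; separates distinct scene colors while tolerating mean-filtered noise |
| `a`, `lambda_thresh` | center-ness threshold on $\rho'\delta'$ | 0.005 | upstream worked value; smaller ⇒ more centers (monotone) |
| `M` | requested superpixel count (`topM`) | unset | use when a fixed budget is needed |
| `epsilon` (px) | BR tolerance | 2 | standard benchmark convention |

## Evaluation metrics

The upstream description names BR and ASA but never defines them; the
standard superpixel-benchmark definitions are adopted. **BR**: fraction
of ground-truth boundary pixels within Chebyshev distance $\varepsilon$
of a predicted boundary pixel. Ground-truth boundaries use the
4-neighbor rule thinned to one side of each interface (the
lexicographically first pixel), so the denominator counts each
interface once; predicted boundaries are two-sided. An image with no
ground-truth boundary scores 1 by convention. **ASA**:
$\sum_s \max_g |s\cap g| / HW$. With multiple annotations per image the
metrics average over annotations (`gt_mode = "max"` available). Both
metrics are invariant to relabeling; ASA is non-decreasing under
superpixel splitting and BR under growing $\varepsilon$ — all
property-tested.

## Synthetic scenes: what they do and do not establish

`make_two_region()`, `make_disk()`, and `make_voronoi_mosaic()` build
piecewise-constant Lab scenes (colors far beyond the $\psi$ gate by
default), convert them to RGB through the package's own inverse
transform, add i.i.d. Gaussian RGB noise (clipped to $[0,255]$), and
carry pixel-exact ground truth. Defaults emulate the stated working
conditions: 240×320 frames, noise sd 2 (8-bit units), 5 Voronoi cells.
One integer seed drives each scene; scenes are byte-reproducible.

They deliberately do **not** model natural-image texture, gradients, or
illumination; a green recovery test establishes the *contract* of the
algorithm (gates, ranking, chains, label lifting), not benchmark
performance on natural images.

Recovery is scored against the **block-quantized** ground truth
`quantize_labels(gt, R)` — the ground truth as representable by any
grid-cell-union segmentation. A pipeline that labels every feature
point with its own cell's true region reproduces it exactly.

## Known limitations

* **Straddling cells are assigned arbitrarily.** The parent links of
  the assignment stage are purely spatial. A grid cell that straddles a
  curved or diagonal region boundary has a mixed block-mean color —
  similar to neither side, hence near-minimal density — and its parent
  chain tends to run *along* the ring of fellow boundary cells before
  entering one region, so whole arcs of straddling cells attach to one
  side. The superpixel boundary then deviates locally by up to one grid
  cell ($R$ px) from the true interface. Measured at $R=8$, noise sd 2:
  the grid-aligned two-region scene recovers perfectly (agreement, BR,
  ASA all 1.0), but the disk scene reaches agreement 0.977 / BR 0.72 /
  ASA 0.988, and 5-cell Voronoi scenes 0.90–0.96 / 0.45–0.58 /
  0.90–0.96 across seeds — far from the BR = 1.0 one might hope for.
  This is a property of the single-pass chain assignment itself (no
  color term, no refinement iterations), not of its implementation; the
  corresponding acceptance expectations are left failing by design.
* $\rho$ is a hard-threshold count, so homogeneous regions are exact
  density plateaus and behavior there is governed by the documented
  tie-breaks.
* Cluster spatial connectivity is not guaranteed;
  `enforce_connectivity()` (or `--enforce-connectivity`) optionally
  splits disconnected components afterwards.
* The upstream BSDS500 figures (BR 95.0 % / ASA 96.3 % at $M = 600$)
  are not reproduced here: they require the external dataset and
  unspecified metric conventions.

## Numerical conventions

0-/1-origin: everything is 1-based (R convention), including CSV
exports. Ties: density ranking and top-M break by ascending raster
index; $\delta$ argmin by earliest rank (above); pixel-to-point by
lower raster index. Distances: Euclidean in pixels; color distances
squared. Degenerate inputs: a single feature point yields one cluster
directly ($\delta$ undefined); all-equal normalization inputs map to 0.
Lab round-trips are exact to 8-bit rounding. The segmentation path
contains no randomness; only scene generators consume seeds.
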