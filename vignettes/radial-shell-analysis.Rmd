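---
title: "Radial shell analysis of chromosome territories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial shell analysis of chromosome territories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshell)
```

## The model

A flattened interphase nucleus in a 2D-FISH image is modeled as an ellipse
with semi-major axis $A$, semi-minor axis $B$, center $M$ and orientation
$\theta$. The counterstain renders the nucleus blue, the chromosome paint
renders the territory red, and the slide background is white. Radial
position is defined through the normalized elliptical coordinate of a pixel
at axis-frame position $(x', y')$:

$$ e = \left(\frac{x'}{A}\right)^2 + \left(\frac{y'}{B}\right)^2 , $$

which is 0 at the center and 1 on the fitted boundary. The ellipse is
partitioned into $N$ concentric shells of **equal area** by boundary ellipses
with semi-axes

$$ a_k = A\sqrt{k/N}, \qquad b_k = B\sqrt{k/N}, \qquad k = 1, \dots, N, $$

so a pixel with coordinate $e$ belongs to the ring whose index is
$\lceil eN \rceil$ counted from the center; the package numbers shells from
the **periphery inwards** (shell 1 = outermost ring, shell $N$ = central
ellipse). Equal areas give the analysis its null model: a territory with no
radial preference deposits $100/N$ percent of its pixels in every shell, so
the per-shell probe percentage profile reads directly as enrichment or
depletion relative to flat.

The per-nucleus readout is the count of nucleus (blue), probe (red) and
other pixels per shell, the within-shell percentages, and the share of total
probe signal per shell. Across a batch, shares are aggregated per group as
mean ± SEM with $\mathrm{SEM} = s/\sqrt{n}$ ($s$ the sample standard
deviation over nuclei, $n$ the number of successfully processed nuclei).

### Assumptions

- One nucleus per image, roughly convex and elliptical, on a light
  background. The row-scan contour bridges concavities: each image row
  contributes its leftmost-to-rightmost span.
- Color classes are separable in RGB. Classification is by per-channel
  distance to reference colors within a tolerance; it uses no spatial
  context.
- The measurement is pixel **area** of classified color, not fluorescence
  intensity. Saturated or thresholded micrographs satisfy this; raw
  intensity images should be segmented/recolored first.
- The analysis is 2D. It is appropriate for flattened nuclei (e.g.
  fibroblasts grown on slides); it does not reconstruct 3D radial position.

## The pipeline, step by step

1. **Pixel classification** (`classify_grid`). A pixel is background,
   nucleus, or probe when all three channels are within `tolerance` of the
   respective reference color; anything else is *other*. The palette is
   validated to be mutually exclusive at the chosen tolerance.
2. **Smudge removal** (`remove_smudges`). Staining specks outside the
   nucleus drag the contour outward. The default *pixel* mode erases a
   non-background pixel when every pixel on the rasterized circle of radius
   `radius` around it is background in the original classification (a
   single pass, so adjacent smudge pixels do not shield each other). Blobs
   wider than the radius escape this test; they are counted, reported, and a
   warning of class `nucshell_large_smudge` is raised — they are *not*
   silently removed, because a blob that size may be a second nucleus. The
   optional *component* mode removes any connected component (8-connectivity)
   other than the largest whose surrounding band is all background.
3. **Contour** (`find_contour`). Per image row, the leftmost and rightmost
   non-background pixel. Probe pixels count as nucleus here: the territory
   lies inside the nucleus, and a territory touching the rim must not dent
   the contour.
4. **Axes** (`estimate_geometry`). From the contour's bounding box, an
   initial midpoint is the box center. The first major-axis endpoint is the
   contour point farthest from this midpoint; the second is found by
   marching from the midpoint away from the first endpoint to the boundary.
   The midpoint is then refined to the mean of the two endpoints, and the
   minor axis is the perpendicular chord through it, found by marching in
   both directions. $A$ and $B$ are half the axis lengths; $\theta$ is the
   major-axis direction, reported in $[0, \pi)$.
5. **Shell assignment** (`count_shells`). Every pixel inside the contour
   gets $e$ from the fitted geometry and a shell index. Pixels inside the
   contour but with $e > 1$ (the real contour is never a perfect ellipse)
   are assigned to shell 1 — they are peripheral by construction.
   Background-classified pixels inside the contour are tallied as *other*:
   they are part of the nuclear area but of no color class.
6. **Aggregation** (`run_batch`, `aggregate_profiles`). Failures (no
   nucleus, degenerate contour) are recorded per image and excluded from the
   aggregate; the output keeps the error message so batches are auditable.

## Parameter choices

- **`n_shells = 5`.** Five equal-area shells resolve a monotone radial
  trend while keeping thousands of pixels per shell in a typical nucleus
  (a 200×100 px nucleus has ~3,100 pixels per shell even in the smallest
  ring), so per-shell percentages are stable at the 0.1% level. Any $N \ge
  1$ is supported; larger $N$ trades per-shell counts for radial resolution.
- **`tolerance = 0.15`.** On a 0–1 channel scale this accepts, e.g., RGB
  (0.9, 0.1, 0.1) as red while keeping pure red, pure blue and white
  mutually exclusive with a wide margin (pairwise channel distances are
  ≥ 1.0 − 2 × 0.15). Raise it for washed-out stains; the palette validator
  errors if classes begin to overlap.
- **`smudge radius = 5`.** The isolation circle must be larger than any
  debris worth erasing and smaller than structures worth keeping. 5 px
  removes typical dust specks (1–3 px) while guaranteeing that nothing
  within 5 px of the nucleus — or any blob wider than 5 px — is touched.

## Numerical choices

- **Sub-pixel vertex localization.** The distance from the midpoint to the
  contour is nearly flat near the major-axis vertex, so the literal
  farthest-pixel rule is noisy: half-pixel radial quantization moves the
  argmax by several degrees of polar angle (we measured axis-angle errors up
  to ~5° on rasterized ellipses of aspect 1.7). `nucshell` therefore refines
  the vertex by fitting a quadratic to contour-point distance versus polar
  angle over a ±15° arc around the farthest pixel, twice. After refinement,
  axis angles are recovered to within 2° for aspect ratios ≥ 1.3 and axis
  lengths to within 2% + 2 px across random ellipses (see
  `scripts/acceptance.R`).
- **Orientation identifiability.** $\theta$ is undefined for a circle and
  ill-conditioned near aspect 1; accuracy claims for $\theta$ are therefore
  stated only for aspect ≥ 1.3. Axis lengths remain accurate at all aspect
  ratios.
- **Boundary marching** uses 0.25 px steps along the ray; the boundary
  crossing is the last in-contour sample, giving endpoints accurate to
  ±0.25 px, well below the pixel-classification noise.
- **Ring boundaries are closed on the outside**: $e$ exactly equal to $k/N$
  belongs to ring $k$ (via `ceiling`), so shell membership is deterministic
  and the shells tile the ellipse exactly.
- **Tie-breaking** for the farthest contour point (smallest $y$, then
  smallest $x$) makes the geometry reproducible bit-for-bit on symmetric
  inputs.
- **Coordinates** are 1-based with pixel centers at integer positions,
  matching R's matrix indexing; all geometry is translation-invariant, so
  results do not depend on this convention.

## The synthetic generator and its realism

`nucleus_spec()` / `make_nucleus_image()` rasterize an analytic ellipse
(pixel centers with $e \le 1$ become nucleus), then add probe signal as

- **blobs**: filled discs at a chosen normalized radial position $u \in
  [0, 1)$ and polar angle — a compact territory;
- **wash**: per-pixel Bernoulli probe with density either constant or an
  arbitrary function of $e$ — a dispersed territory. A constant density is
  the uniform null; `function(e) 0.45 * exp(-1.5 * e)` mimics an
  interior-biased, gene-rich-like territory and
  `function(e) 0.45 * exp(1.5 * (e - 1))` a peripheral, gene-poor-like one;
- **smudges**: discs outside the nucleus, to exercise the cleanup.

Every fixture carries exact ground truth: the analytic geometry and a
brute-force per-shell tally computed from the true (not recovered)
parameters. This is what makes the acceptance checks sharp — equal-area
fidelity, geometry recovery, and end-to-end share recovery are all measured
against truth, not against the package's own output.

Realism limits: real nuclei are not exact ellipses, have intensity
gradients, anti-aliased edges and occasionally touch; the generator produces
hard-classified, isolated, exactly elliptical nuclei. The generator is
therefore suitable for validating the *geometry and counting* machinery, not
for benchmarking the color classifier on microscope noise. Problem sizes in
the validation scripts (axes 40–150 px, aspect ≤ 3, images a few hundred
pixels square) are this package's own choices, matched to typical
flattened-fibroblast micrographs.

## Worked reference example

On a published sample nucleus (401 × 385 px image, five shells), the
pipeline's counting stage reproduces the reported per-shell composition: for
printed counts of 10,936 blue and 1,192 red pixels among 12,128 total in
shell 2, `shell_profile()` yields 90.2% blue and 9.8% red, matching the
reported values; the same holds for all five shells. This arithmetic check
is asserted in the test suite. (The original sample images are no longer
retrievable, so the check operates on the printed counts rather than the
image.)

## Limitations and open questions

- **Concave or lobed nuclei** are bridged by the row-scan contour; their
  fitted ellipse overestimates the area and the outer shells absorb the
  error. A segmentation-based contour would be a natural extension.
- **Touching nuclei** are not split; the large-smudge warning will fire for
  a second nucleus, but the user must crop.
- **Area, not intensity.** Probe quantification by classified-pixel area
  discards intensity information; partial-volume pixels at territory edges
  are all-or-nothing.
- **Shell-boundary pixels** are assigned wholly to one ring. At $N = 5$ and
  nuclei ≥ 40 px semi-minor axis, the resulting per-shell area imbalance is
  below 2% (measured over random ellipses in `scripts/acceptance.R`);
  for very small nuclei it grows, which is why a minimum nucleus size on
  the order of tens of pixels per axis is recommended.
- The **midpoint is refined once** (after the major axis); we do not iterate
  geometry fitting to convergence. On convex nuclei a second iteration
  changes the axes by less than the marching step, so it is omitted.
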