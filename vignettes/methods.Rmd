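---
title: "Methods: morphology, cell networks, progressions and spheroid invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology, cell networks, progressions and spheroid invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemorph)
```

# The model

clonemorph phenotypes clonal cell populations at three scales and ties the
scales together:

1. **Single cells** (2D). From an instance-segmented label image each cell
   contributes area, circumference, circularity $4\pi A/P^2$, and aspect
   ratio (major/minor axis of the inertia-equivalent ellipse). A
   population snapshot summarizes each property by mean, population
   variance, and Shannon entropy
   $H(x) = -\sum_i P(x_i)\,\ln P(x_i)$ over non-border cells, alongside
   the confluency (foreground pixel fraction), which serves as the density
   axis throughout.
2. **Cell networks** (2D). Cells are nodes; an edge joins two cells whose
   minimum boundary-to-boundary distance is strictly below 5 µm. From the
   network we derive the mean, variance and entropy of the vertex degree,
   the average colorability $\langle\chi(G)\rangle = \sum_i \chi(c_i)/n$
   (mean chromatic number over connected components, a proxy for maximum
   achievable packing density), the component number, the entropy of the
   component vertex-mass distribution, the relative mass of the largest
   component $|c_1|/|G|$, and the box-counting fractal dimension
   $\dim_{box}(S) = \lim_{\epsilon\to 0} \log N(\epsilon)/\log(1/\epsilon)$
   of the rasterized foreground.
3. **Spheroids** (3D). A 75 µm window of z-slices (fifteen slices at 5 µm)
   from the centre of a spheroid is max-projected, binarized, and
   decomposed into the main body, protrusions, and disseminated regions.
   Six invasion metrics (protrusion count, mean and maximum tip-to-centroid
   length; disseminated-region count, mean and maximum centroid-to-centroid
   distance) are min-max normalized across the clone panel and averaged
   into the composite score
   $\mathrm{invasion3D} = (\bar n_p + \bar n_c + \overline{avg}_p +
   \overline{avg}_c + \overline{max}_p + \overline{max}_c)/6 \in [0, 1]$.

Because a clone's morphology changes systematically as its culture
densifies, a clone is characterized not by one snapshot but by its
**morphological progression**: each property is regressed on confluency
(polynomial, degree 2 by default) over one subculture cycle, and the fits
are evaluated at low/mid/high confluency anchors (0.15/0.40/0.70) to give
the per-clone **growth-variable vector** with suffixes `_l`, `_m`, `_h`.
Density, not time, is the independent variable: the fits, and hence the
growth variables, are invariant to the acquisition order of the snapshots.
Clones are then clustered hierarchically (Ward linkage on Euclidean
distance over z-scored growth variables) in two stages: a k = 2 cut into
superclasses (the parental-line split) and k = 3 subclass cuts within each
superclass. Finally, Spearman correlation matrices over clones relate 2D
growth variables (by default at the `_m` anchor, one value per clone) to
the 3D metrics, visualized as threshold graphs (|r| > 0.8 for the
all-variable graph; |r| > 0.3 for the star graph around invasion3D only).

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| adjacency threshold | 5 (strict `<`) | µm | defines cell-cell adjacency; a gap of exactly 5 µm yields no edge |
| polynomial degree | 2 | — | progression trends are smooth and low-order; higher degrees overfit small image panels |
| confluency anchors | 0.15 / 0.40 / 0.70 | fraction | low/mid/high density evaluations of each fitted trend |
| χ exact limit | 20 | nodes | components up to this size are solved exactly by backtracking; larger ones get a flagged greedy (largest-first) upper bound |
| box sizes | powers of 2, from 2 px to min(dim)/4 | px | default box-counting grid, anchored at the image origin |
| projection window | 75 | µm | fifteen 5-µm slices centred on the spheroid |
| spheroid min component | 50 | µm² | suppresses noise specks before shape analysis |
| protrusion core radius | 0.8 × equivalent body radius | µm | opening radius separating body core from protrusions |
| min protrusion extent | 20 | µm | radial extent below which a residue component is not a protrusion |
| correlation thresholds | 0.8 / 0.3 | \|r\| | all-variable graph / invasion-only star graph |

All of these are surfaced in `pipeline_config()`, so a run is auditable
from its `config.yaml`.

# Numerical choices

**Coordinates.** Pixels are (row, col); physical coordinates are pixel
centres at `(index - 1) * pixel_size` µm. Boundary distances are computed
between boundary-pixel centres; bounding-box pruning makes the pairwise
computation exact yet fast (identical to brute force, which the tests
verify against the generator's analytic polygon gaps).

**Perimeter.** Raw boundary-pixel chain lengths overestimate smooth
boundaries resolution-dependently, which would depress circularity. We
therefore measure the arc length of the moving-average-smoothed outer
contour polygon and add $\pi$ for the half-pixel band between pixel
centres and the true boundary (the Minkowski dilation of a closed curve by
radius 1/2 adds $2\pi \cdot 1/2$). On discs this is accurate to ~0.5% and
circularity clips at 1; on large squares circularity converges to
$\pi/4$.

**Entropy binning.** Continuous shape properties use Freedman–Diaconis
bins (scale-adaptive, avoids an arbitrary bin count); discrete quantities
— vertex degrees — use exact integer bins. $0\ln 0 := 0$.

**Variance.** Population (not sample) variance: a snapshot is the full
observed population of the image.

**Border cells.** Cells touching the image border are excluded from shape
summaries (their truncated geometry biases morphology) but kept as network
nodes (they still occupy topology).

**Chromatic numbers.** Exact values come from iterative-deepening
backtracking (greedy clique lower bound, greedy largest-first upper bound,
colour-symmetry breaking, descending-degree vertex order). Components
larger than the exact limit fall back to the greedy upper bound and the
result carries an `exact = FALSE` flag plus a warning — cell adjacency
components are near-planar and small, so the exact path is the norm.

**Box counting.** The default box sizes are powers of 2 from 2 px up to a
quarter of the image side, with the grid anchored at the origin — the
generic choice for foreground masks, and it recovers dimension 2.0 for
filled regions and 1.0 for curves. For fixtures with a known
self-similarity ratio the estimator accepts matched box sizes (powers of 3
for a Sierpiński carpet), along which the count sequence follows the exact
scaling relation $N(3^{-k}) = 8^k$; dyadic boxes on a ternary fractal
truncated at finite depth systematically flatten the fitted slope
(≈1.74 instead of 1.893 at depth 4), which is a property of the fixture,
not of the estimator.

**Spheroid centroid.** Tip-to-centroid lengths and centroid-to-centroid
distances are measured from the centroid of the *opened* main body (the
core): the centroid of the full body is dragged towards the longest
protrusions, biasing every length by up to several micrometres on
asymmetric spheroids.

**Binarization.** Global Otsu threshold with a fixed-threshold override,
followed by minimum-area filtering and hole filling. Opening is computed
exactly through the Euclidean distance transform rather than a discrete
brush.

**Degenerate inputs.** Empty images yield empty (valid) networks; empty
networks refuse metric computation with explicit errors; constant
variables are dropped from clustering (with a warning) and produce missing
Spearman correlations; a metric constant across clones normalizes to 0 in
invasion3D with a warning.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's guarantees are demonstrated.

*Populations* are perturbed ellipses (semi-axes 8–16 µm, smooth radial
perturbation of relative amplitude 0.08) placed by rejection sampling at a
target confluency, at 1 µm/px. Each cell is a polygon, so area, centroid
and pairwise boundary gaps have analytic ground truth; planted adjacency
is the set of pairs with polygon gap < 5 µm. Placement rejects gaps inside
an ambiguity band of ±2 px around the threshold so that rasterized and
analytic distances always agree on which side of the threshold a pair
falls — without the band, a pair at 4.99 µm could rasterize to 5.01 µm and
make exact recovery impossible for reasons unrelated to the method.

*Progressions* draw property values as planted quadratic(confluency) plus
Gaussian noise.

*Spheroids* are a ball (radius 200 µm) with capsule protrusions whose tip
caps end exactly at the planted tip-to-centroid length, and disc-shaped
disseminated regions at planted centroid distances, rendered into ≥15
slices at 5 µm spacing and 2 µm/px with additive Gaussian intensity noise
(sd 0.03 on a [0, 1] scale, i.e. SNR ≈ 25 for the 0.75 foreground-
background contrast). Structures interleave on equally spaced directions
and collisions raise an error rather than silently merging.

What the generator does *not* emulate: phase-contrast texture,
segmentation errors (segmentation is a pluggable input — its quality is
scored by the `evaluate_segmentation`/`prune_duplicates` tools, not
simulated), cell division and motility dynamics, uneven illumination, and
partial-volume effects in z. Passing tests therefore demonstrate the
correctness of the measurement pipeline given a segmentation, not the
robustness of any particular segmenter.

# Design choices on open points

- **Mask format**: labels are relabeled to consecutive integers at ingest;
  TIFF for images, GraphML for networks, CSV for tables.
- **Linkage**: Ward on Euclidean distance over z-scored variables — the
  standard choice for compact morphological classes; configurable.
- **Growth-variable naming**: anchor evaluations `<property>_l/_m/_h`
  rather than raw polynomial coefficients; anchors outside the observed
  confluency range are still evaluated but flagged as extrapolated.
- **Duplicate-mask pruning**: greedy suppression by descending confidence
  with mask-IoU threshold 0.5 and smaller-index tie-break — deterministic
  and idempotent.
- **2D variables in correlations** enter at the `_m` anchor by default
  (one value per clone), configurable to other anchors.
- **Embedding**: `embed_clones()` is a deterministic principal-component
  projection with a fixed sign convention — a visual aid only; no
  downstream result depends on it.
- **Correlation p-values** are not used for graph edges; edges are
  thresholded on |r| only.

# Problem sizes used in the packaged checks

The bundled tests and the reproduction script run entirely on generated
data at desk scale, chosen to exercise every code path while keeping a
full run fast: populations of 25–120 cells, panels of 4–6 clones at 3–4
densities for the end-to-end pipeline, 60-clone panels for cluster
recovery, 10–50 seeded spheroid stacks (17 slices, ~660 px square), and
oracle batteries of up to 1000 random graphs of ≤12 nodes. Under these
conditions adjacency recovery is exact, chromatic numbers agree with
independent backtracking everywhere, protrusion/dissemination counts are
recovered exactly with lengths within 2 px, and the nested clustering
attains ARI 1.0 at 4× between/within separation.

# Known limitations

- The full supplementary growth-variable list of the original assay is not
  re-derivable from measurements alone; the anchor scheme here is a
  declared, documented convention covering the properties the package
  measures.
- Greedy chromatic upper bounds (components > exact limit) can exceed the
  true χ; they are always flagged.
- The box-counting slope on finite rasters depends on the box-size range;
  the defaults are stated above and both the sizes and the counts are
  returned with the estimate.
- Protrusions thinner than 2 px or shorter than the minimum radial extent
  are not detected; disseminated regions overlapping the body in
  projection are merged into it.
- Spearman correlations over small clone panels are noisy; at n = 10
  clones a null variable still crosses |r| > 0.3 roughly a third of the
  time, so the 0.3-threshold star graph is a screening view, not an
  inference.
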