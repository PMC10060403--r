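---
title: "gridspot: models and methods for grid-structured screening images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gridspot: models and methods for grid-structured screening images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridspot)
```

## The problem

Miniaturized screening platforms — droplet microarrays (DMA), well plates,
microwell chips — arrange hundreds of independent experiments on a
rectangular lattice of roughly circular spots. Image-based readouts
(fluorescence microscopy, flatbed scanners) therefore decompose naturally
into a *macro* problem, recovering the lattice geometry shared by all
spots, and a *micro* problem, analyzing the content of each spot: counting
cells, fusing live/dead stains into a viability fraction, or quantifying a
colorimetric signal. gridspot implements this two-level pipeline in R,
together with the assisted-annotation utilities (diverse sample ordering,
classical pre-annotation, inspection metrics) that support building
training data for learned components, and a synthetic scene generator that
plants exact ground truth for every stage.

Learned predictors are deliberately *not* shipped. Everywhere the original
workflow would use a neural network (element scoring, distance-map
prediction, feature embedding, pre-annotation masks), gridspot exposes a
pluggable external-input contract with a classical default (Otsu
thresholding, exact Euclidean distance transform, histogram/moment/edge
descriptors). The lattice logic, fusion logic and metrics — the substance
of the pipeline — are first-class, tested code.

## The grid model

A grid is parameterized by counts $(R, C)$, the center of element
$(0, 0)$, pitches $(p_x, p_y)$ in pixels, a rotation $\theta$ in degrees
and a spot radius $r$:

$$\mathrm{center}(i, j) \;=\; \mathbf{o} + \mathbf{R}(\theta)
\begin{pmatrix} j\,p_x \\ i\,p_y \end{pmatrix},
\qquad 0 \le i < R,\; 0 \le j < C.$$

Pixel coordinates are $x =$ column, $y =$ row, 0-based at pixel centers;
$\mathbf{R}(\theta)$ is the usual counter-clockwise rotation acting on
$(x, y)$. Because an unlabeled rectangular lattice is invariant under
90-degree turns, $\theta$ is only identifiable on a 90-degree fold; we
restrict it to $(-45, 45]$ and document this as a limitation rather than
guessing an orientation.

### Detection pipeline

1. **Preprocess** — luminance reduction (Rec. 709) and percentile
   normalization: the `p_low` percentile maps to 0 and `p_high` to 1
   (defaults 1 and 99), clipped. A constant image yields zeros with a
   warning, not an error, so batch runs degrade gracefully.
2. **Element segmentation** — Otsu's threshold by default, a percentile
   threshold, or an external per-pixel score raster thresholded at 0.5
   (the hook for a learned segmenter).
3. **Post-processing** — morphological opening with a disc (default
   radius 1 px) and an area filter keeping components within
   $(0.3, 3) \times \mathrm{median\ area}$, which removes specks and
   merged elements with no tuning per image.
4. **Rotation** — for every element centroid the displacement to its
   nearest neighbour is computed; along a lattice these displacements
   point along grid axes, so each angle is folded modulo 90 degrees into
   $(-45, 45]$ and the *circular median* of the folded angles is
   returned. The median is robust to a minority of spurious or missing
   detections; the fold makes the estimator exact for lattices rotated by
   any multiple of 90 degrees.
5. **Lattice fit** — centroids are de-rotated, each axis independently is
   clustered into grid lines by single-linkage with a gap threshold of
   half the median nearest-neighbour spacing; pitch is the median of
   consecutive line differences, the origin is the first line center
   rotated back, and the spot radius is the median equivalent radius
   $\sqrt{A/\pi}$. When an expected shape is supplied, interior lines
   missing because a spot failed to detect are interpolated whenever the
   pitch divides the gap within 10%; any remaining mismatch is an error
   rather than a silent guess. RANSAC-style fitting was considered and
   rejected: at desk scale the cluster-then-median estimator already
   tolerates the outlier rates the area filter lets through.

The semi-automated fallback (`semi_automated_grid()`) completes a partial
parameterization from clicked element centers with documented,
deterministic derivation rules — two opposite corners plus counts and
rotation, or three corners when the rotation itself is unknown.

### Accuracy accounting

The acceptance suite checks every fitted parameter against planted truth
on twenty noisy synthetic scenes at a 3% relative-error bound. A relative
error is ill-posed for the rotation angle, whose true value may be
arbitrarily close to zero in the stated $-10^\circ..10^\circ$ range; the
angular error is therefore compared against 3% of the 45-degree
half-period (1.35 degrees), while counts must be exact and origin error is
the Euclidean distance over the origin norm. In practice the estimator
stays well under 0.3 degrees and 1% on all other fields. At the stated
contrast (spot level 0.8 vs background 0.1) pixel noise of
$\sigma = 0.05$ never flips a thresholded pixel, so the residual error is
dominated by deterministic disc rasterization bias — the acceptance
statistic is then identical across RNG seeds, which is expected, not a
bug.

## Instance segmentation

The micro-level detector follows the distance-map / watershed design:

* `predict_distance_map()` — default: Otsu foreground, then the exact
  Euclidean distance transform (two-pass lower-envelope algorithm in
  C++). An externally predicted map is accepted if it is non-negative and
  shape-matched, so a trained network can replace the classical default
  without code changes.
* `watershed_instances()` — seeds are regional maxima with prominence at
  least `h` (computed via the h-maxima transform, i.e. grayscale
  reconstruction of `dmap - h` under `dmap`), thinned to one pixel per
  plateau and filtered to a pairwise distance of at least
  `min_seed_distance`; flooding runs on $-$dmap restricted to dmap $> 0$
  with a deterministic FIFO tie-break, so touching objects split along
  the neck between their maxima and re-runs are bit-identical. Defaults
  `h = 1` px and `min_seed_distance = 3` px are documented choices — the
  source workflow states no values — sized to the 3–4 px cell radii of
  the synthetic scenes; both are configurable.
* `extract_features()` — area, centroid, mean intensity, and the axis
  lengths of the ellipse with the region's normalized second central
  moments ($\mathrm{major} = 4\sqrt{\lambda_{\max}}$), from which
  eccentricity $e = \sqrt{1 - (b/a)^2}$ follows. This definition was
  adopted because it reproduces, to three decimals, the eccentricity of
  all eight rows of the published per-instance feature table from their
  printed axis lengths — verified in the test suite before the
  implementation was written.

## Viability fusion

Channels: Hoechst stains every nucleus (the total-count anchor), Calcein
marks metabolically active cells, PI enters ruptured membranes. The
nearest-neighbour fusion is made concrete as *mutual* nearest neighbours
by centroid distance with a greedy ascending-distance resolution and a
distance cap defaulting to the median Hoechst equivalent diameter; the
source describes only the algorithm family, so the cap and the
mutual-NN choice are package decisions, tested against an exhaustive
minimum-total-distance oracle in the regime where that optimum is unique.
A cell is **alive** iff Calcein-positive and PI-negative. Two observed
phenomena are handled explicitly: dying cells that stain faintly for
Calcein while already PI-positive (matched in both channels, counted
dead) and Hoechst-only cells with inactive metabolism but intact membrane
(matched in neither, counted dead). Calcein or PI instances with no
Hoechst anchor are reported as anomalies and never counted as cells.
Viability with zero anchored cells is `NA`, an explicit undefined
sentinel, never 0.

## Colorimetric quantification

An RGB scanner image is scalarized by a registered transform (luminance,
single channel, arbitrary linear combination, HSV hue), aggregated per
spot over the ROI disc mask (median by default, robust to edge
artifacts), and calibrated against known values: Pearson correlation plus
a monotone piecewise-linear map fitted by isotonic regression, direction
chosen by the sign of the correlation. Any monotone family would satisfy
the "convertible into each other" contract; isotonic regression was
chosen because it is assumption-free and exactly monotone on the sample.
The transform used in the published pH experiment is not specified there,
so no pH-specific default is claimed; the acceptance surrogate declares
its transform (single channel) explicitly.

## Annotation support

* `embed_images()` + `reduce_pca()` + `heterogeneity_order()` — the
  sample-selection chain: a pluggable embedder (classical default: 32-bin
  histogram, four intensity moments, edge-density statistics; an external
  feature matrix stands in for a pretrained network), PCA to ten
  dimensions with a deterministic sign convention, and farthest-point
  (max–min) ordering started at the medoid. Ties break by ascending
  identifier so orders are reproducible.
* `preannotate()` — Otsu or percentile threshold masks; learned masks
  enter only as external inputs.
* `dice()` and `aji_plus()` — inspection metrics. The "advanced"
  aggregated Jaccard index is interpreted as the optimal-assignment
  variant: truth and predicted instances are matched one-to-one by an
  exact Hungarian solver maximizing summed IoU, which repairs the
  over-penalization of the greedy variant; the published text cites but
  does not define it, so this interpretation is a documented decision,
  tested against exhaustive assignment enumeration.

## The synthetic world

`generate_grid_scene()` plants bright discs (level 0.8) on a darker
background (0.1), rotates the lattice about the image center before
adding clipped Gaussian pixel noise, and records the exact grid. The
stated acceptance world uses $\sigma = 0.05$; the generator default is a
milder 0.02 for interactive use. `generate_cell_scene()` plants
non-overlapping cells per spot as Gaussian-shaded discs whose profile is
truncated at the mask edge (edge value 0.2 of the peak, which fixes the
Gaussian width from the drawn radius). The hard support is a deliberate
departure from infinite Gaussian tails: it guarantees that any global
threshold separates planted cells, which is what makes the *exact*
planted-viability recovery criterion meaningful rather than luck. The
planted live count is `round(alive_fraction * n)`, so stated fractions
are recovered exactly; dead cells join the Calcein channel faintly
(amplitude 0.15) with an explicit probability defaulting to 0 — the
phenomenon is described in the source without a rate.
`generate_colorimetric_scene()` colors spot interiors by a monotone
latent-to-RGB model plus i.i.d. pixel noise on a light-grey background.

What the generator does **not** emulate: point-spread blur, vignetting,
uneven illumination, chromatic shift, debris, or out-of-focus planes. A
green test therefore establishes algorithmic correctness against the
stated world, not robustness to real microscope pathologies; the
external-predictor hooks exist precisely because real data may need a
learned front end.

Noise and density statistics of the original DMA images are not published;
the defaults here (noise 0.02, 3–4 px cell radii, 25 cells per 40 px
spot) were chosen once for testability and realism at desk scale and are
not revisited.

## Numerical and convention choices

* Rasters are numeric matrices in $[0, 1]$, `nrow` = height; writers
  quantize to 8/16-bit integers on export (16-bit default, matching
  high-bit-depth acquisition).
* Bounding boxes are half-open; connectivity is 4-way everywhere;
  component labels are consecutive in raster-scan order.
* Otsu uses 256 bins with the first maximum on ties; watershed and
  matching tie-breaks are documented and deterministic, so every pipeline
  stage is idempotent and re-runs are byte-identical.
* File formats are deliberately minimal and dependency-free: baseline
  uncompressed TIFF (8/16-bit, gray/RGB, multi-page) and non-interlaced
  PNG (zlib via R's `memCompress`), plus CSV and JSON. The pipeline
  configuration file is JSON rather than YAML: no YAML parser is part of
  the supported dependency set, and JSON meets the single
  human-readable-config contract with `jsonlite` alone. Gigapixel tiled
  reading of full slide scans is out of scope; rasters are read whole.

## Known limitations

* Rectangular lattices only: no hexagonal grids, per-row pitch variation
  or perspective distortion.
* Rotation identifiable only modulo 90 degrees.
* No training of any predictor, no 3-D segmentation, no tracking, no
  dose–response fitting, no GUI or remote execution.
* The original rotation/robust-estimation algorithms are published only
  by behavioral description; the implementations here are reconstructions
  satisfying that description, not ports, and are flagged as such.
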