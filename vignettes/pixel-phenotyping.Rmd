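---
title: "Segmentation-free pixel phenotyping of imaging mass cytometry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-free pixel phenotyping of imaging mass cytometry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imaging mass cytometry (IMC) rasterizes a tissue section at a ~1 µm pitch
and reads out one intensity channel per metal-tagged antibody — typically
20–40 markers per run. The classical analysis route segments cells first
and phenotypes the segments. In densely packed tissue (germinal centers,
lymphoid aggregates, epithelium) segmentation is the weakest link:
membranes of neighboring cells blur into each other at 1 µm and nuclear
markers are an unreliable proxy for cell boundaries. pixplore takes the
segmentation-free route instead: every *pixel* is treated as an
observation in marker space, phenotyped by clustering, and painted back
onto the raster. Aggregates of same-class pixels then read as cells or
structures without a segmentation model ever being fit.

The package implements the complete chain: variance-stabilizing
preprocessing, a multi-scale landmark hierarchy so that embeddings stay
tractable on full ROIs, density-based clustering of landmark embeddings
with drill-down, signature-driven class naming, overlay rendering, and
region-group quantification of double-positive pixels with an exact
one-tailed Mann–Whitney test.

## Preprocessing

Raw IMC intensities are ion counts: non-negative, right-skewed,
variance roughly proportional to the mean. Two conventional operations are
applied per channel:

* **Maximum-signal threshold.** The q-th percentile (default q = 98,
  linear interpolation between order statistics — the same convention as
  `quantile(type = 7)`) of all pixels in the ROI is computed and the
  channel is clipped there. This suppresses the rare hot pixels that
  otherwise dominate both display scaling and distance computations. The
  operation never raises a pixel and changes at most
  `ceiling((1 - q/100) * N)` pixels. On its actual input domain — integer
  ion counts, whose upper tail is tied — it is also idempotent; on
  hypothetical all-distinct continuous data no interpolating percentile
  can be (the re-quantile interpolates between the largest unclipped
  value and the threshold).
* **Arcsinh transform**, `asinh(x / c)` with cofactor `c = 5`, the
  standard cytometry variance stabilizer: linear for counts below the
  cofactor, logarithmic above, exactly 0 at 0, strictly monotone. Order
  statistics of every channel are preserved, so positivity gates commute
  with the transform.

Clipping is applied to raw counts *before* the transform, so the threshold
stays interpretable in count units. Both parameters are configuration
(`percentile`, `cofactor`); the defaults are the values used throughout.

## The landmark hierarchy

A full ROI is ~2.5×10⁵ pixels; pairwise embedding of that many points is
neither tractable nor useful as a first view. The package builds an
HSNE-style hierarchy:

1. **kNN graph** (default k = 30) on the pixels' transformed marker
   vectors, Euclidean metric. Edge weights decay with distance,
   `exp(-(d/σᵢ)²)` with σᵢ the mean neighbor distance of the source pixel
   (duplicate pixels — common in zero-inflated IMC backgrounds — get
   uniform weights).
2. **Landmark selection** by random walks: 100 walks of length 50 from
   every node; nodes visited more than 1.5× the expected count become the
   next scale's landmarks. These defaults follow the HSNE literature and
   are exposed as `walk_params`.
3. **Area of influence** by Monte-Carlo absorption: 100 walks per finer
   point, each terminated at the first landmark hit (cap 500 steps);
   normalized absorption frequencies form the row-stochastic influence
   matrix. Points whose walks never reach a landmark (isolated
   components) are deterministically assigned to their nearest landmark
   in marker space so that rows always sum to one. Landmark weights are
   the influence-weighted sum of the finer weights, so at every scale the
   weights sum to the pixel count — a conservation law the tests pin to
   ±10⁻³.
4. **Next-scale similarities** come from the overlap of areas of
   influence, `t(I) diag(w) I`; the strongest overlaps per landmark form
   the walk graph one level up. Three scales (pixels → tissue → detail)
   are the default.

Drill-down assigns every pixel to the landmark holding its largest
composed influence (ties to the lowest landmark index, so the operation is
deterministic) and extracts the pixels flowing into a selection — the
"select tissue pixels, re-embed, select CD45⁺/dim, re-embed" loop used in
pixel cytometry. Because the assignment is a partition, drilling into a
partition of the landmark set partitions the pixels.

## Embedding and weighting

Each scale can be laid out in 2-D by exact t-SNE (perplexity 30, 1000
iterations, early exaggeration 12 for 250 iterations, learning rate 200,
deterministic given the seed; the O(n²) gradient is computed in C++ and is
practical up to a few thousand landmarks, which is precisely what the
hierarchy delivers). Similarities are perplexity-calibrated Gaussian
conditionals on the kNN graph of the scale's points; at landmark scales
the landmarks are represented by their marker profiles. The Monte-Carlo
overlap matrix is deliberately *not* used as the embedding similarity: at
100 walks per point its rows are too sparse to carry a calibrated
distribution, while it remains perfectly adequate for choosing the
next-scale walk graph.

Landmark mass enters the objective with multiplicity semantics — a
landmark of weight w behaves as w coincident points in both the attractive
and the repulsive term. Mass is tempered as `w^weight_power` with default
0.5. The reason is a measured failure mode, not taste: IMC backgrounds are
zero-inflated, so a handful of landmarks can represent half the ROI. With
raw masses those few points absorb essentially the entire attraction
budget and the remaining landmarks disperse into a structureless cloud
(cluster purity on the bundled demo drops from ~0.9 to ~0.33). The square
root preserves the ordering of masses — heavy landmarks still anchor
denser islands and dominate the mean-shift density — while bounding their
dominance. `weight_power = 1` restores the literal weighting; `0` ignores
mass entirely.

## Gating: from embedding to named classes

Clusters are density modes: weighted Gaussian mean-shift on the 2-D
embedding, bandwidth defaulting to 5% of the embedding bounding-box
diagonal. Every point ascends the weighted kernel density; converged
positions within half a bandwidth are merged by connected components, and
cluster numbering is ordered by mode position, so the procedure is
deterministic and invariant to point order. Mean-shift was chosen over
k-means-family algorithms because it needs no cluster count and its modes
correspond to the visual islands a user would gate by hand.

Labels expand to pixels through the argmax-influence assignment, giving a
label map on the original raster. Clusters are then named against an
ordered signature table (first match wins, mirroring hierarchical manual
gating): a cluster is positive for a marker when its member median exceeds
the marker's positivity threshold — by default the 60th percentile of the
analyzed pixels' transformed intensities, with the 30th–60th band defined
as "dim". These quantile gates are an operational stand-in for
interactively drawn gates, which are inherently unrecoverable; both
quantiles are configuration.

Rendering maps each class to one of at most nine fixed, maximally
distinct colors over a black background or a grayscale base channel. The
nine-class cap is a renderer contract (more classes raise an error asking
the user to merge or drop), the palette is fixed in the package so figures
reproduce, and the color↔class mapping is a bijection the tests invert
pixel for pixel. No resampling ever occurs: one output pixel is one input
pixel.

## Quantification

For a marker pair (e.g. CD161/CD69), a pixel is double-positive when both
channels sit at or above their thresholds (boundary inclusive; default
threshold = positivity quantile × the channel's 98th-percentile
maximum-signal value). Counts and fractions are computed inside each
annotated region; fractions (not raw counts) are compared between region
groups because the contrasted regions are area-matched by design, and raw
counts remain in the output table.

Group comparison uses a one-tailed Mann–Whitney U test computed from
mid-ranks. For combined sizes ≤ 20 without ties the p-value is exact by
full enumeration of all C(n₁+n₂, n₁) label arrangements — instant at the
7-vs-5 design this tool targets, where complete separation gives
p = 1/792 ≈ 0.00126. With ties or larger samples the normal approximation
with tie and continuity corrections is used, and a U exactly at its null
mean returns p = 0.5 by symmetry convention.

## The synthetic-data generator

All tests and the acceptance script run on generated images, because the
original donor-tissue acquisitions live in external repositories and are
not desk-scale inputs. A `synthetic_spec` plants rectangular and disc
regions (pixel-center rasterization, so areas are exactly checkable by
point-in-shape enumeration), assigns classes to regions with mixing
fractions, and draws intensities per channel as Poisson (mean = rate) or
lognormal (mean × exp(N(0, σ²))) noise around per-class means —
count-like, non-negative, zero-inflated where a marker is absent, which
reproduces the degenerate-duplicate structure real IMC backgrounds have.
Seeds are explicit fields; identical spec + seed is bit-identical output.

The bundled LF study design (`lf_study_spec()`) mirrors the quantification
design at desk scale: a 160×220 µm tissue raster with an epithelial band,
a stromal field, 7 lymphoid-follicle discs rich in B/T/ILC pixels with
planted CD161⁺CD69⁺ co-expression, and 5 area-matched non-LF control
boxes. What the generator does *not* emulate: channel spillover,
instrument drift, hot pixels, 3-D partial-volume effects, or spatial
intensity gradients. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration on clean planted structure, not
robustness to those instrument artifacts.

## Numerical choices and problem sizes

* Percentile convention: type-7 linear interpolation, stated and tested
  against a brute-force order-statistic oracle.
* kNN ties: broken by (distance, row index) on the exact search path used
  for small inputs (≤ 2048 rows); larger inputs use a kd-tree.
* Influence rows: renormalized to sum to 1; deviation tolerance 10⁻⁶.
* Hard assignment ties: lowest landmark index.
* Mean-shift: convergence when the largest shift drops below 10⁻⁶ ×
  bandwidth; mode merge radius bandwidth/2.
* Degenerate inputs: single-point embeddings and single-point clusterings
  return trivial layouts with a warning rather than failing; hierarchies
  that would produce scales with fewer than 10 landmarks are truncated
  with a warning.
* Problem sizes used by the test suite: the conservation and capacity
  checks build the hierarchy on a 2.5×10⁵-pixel, 19-marker table (the
  size of one full ROI); recovery checks use 60×60-pixel four-class
  images over five seeds; the end-to-end demo runs at 100×140 to 160×220
  pixels. These sizes were chosen as the smallest that still exercise
  each property at realistic scale.

## Limitations

* Exact t-SNE is O(n²); embedding the raw pixel scale of a full ROI is
  out of reach by design — that is what the landmark hierarchy is for.
* Quantile positivity gates approximate, but cannot recover, interactive
  gate boundaries; signature order matters when phenotypes overlap.
* The Monte-Carlo influence estimates carry sampling error bounded by the
  walk counts; the conservation invariants hold exactly after row
  normalization, but individual influence entries are stochastic.
* No spillover compensation, hot-pixel removal, or multi-ROI batch
  normalization is provided.
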