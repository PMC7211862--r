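---
title: "Methods and design notes for nmjmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for nmjmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjmetrics)
```

## The measurement problem

A neuromuscular junction (NMJ) is imaged as a two-channel confocal z-stack:
one channel stains the pre-synaptic nerve terminal, the other the
post-synaptic acetylcholine receptors (AChR). Morphometric phenotyping of
NMJs in health and disease rests on a standard panel of 19 variables — 7
pre-synaptic (terminal area and perimeter, branch counts, branch lengths,
and the composite "complexity" score), 11 post-synaptic (AChR and endplate
areas/perimeters, endplate diameter, cluster count and its derivatives
"fragmentation" and "compactness", nerve–receptor "overlap" and contact
area), and the axon diameter. `nmjmetrics` computes this panel from
maximum-intensity projections of calibrated TIFF stacks, batch-capable and
scriptable, with the thresholding and axon processing steps — the parts
that genuinely need human judgement — supplied as explicit inputs rather
than interactive clicks.

## The seven-stage flow

`analyze_image()` runs a fixed guided sequence: (1) per-channel maximum
projection; (2) AChR threshold; (3) nerve threshold; (4) axon
measure/erase; (5) post-synaptic measures and endplate footprint; (6)
segmentation check and cluster count; (7) record assembly.
`nmj_stages()` enumerates the stages; `--verbose` logs each boundary.
Batch runs (`analyze_folder()`) process files in lexicographic order and
isolate per-image failures.

Every record passes an internal consistency audit (`validate_record()`):
average branch length × branch count = total length, fragmentation =
1 − 1/n clusters, overlap = contact / AChR area × 100, compactness ≤ 100.
A violation is a pipeline bug, never silently recorded.

## Derived-variable formulas

* complexity = log10(branches × branch points × total branch length / 100);
  recorded as missing (with a QC flag) when any factor is zero, keeping the
  CSV numeric while flagging the degenerate terminal.
* fragmentation = 1 − 1 / (number of AChR clusters).
* compactness (%) = AChR area / endplate area × 100.
* overlap (%) = contact area (nerve ∩ AChR) / AChR area × 100.

## Binary machinery and its conventions

**Thresholding.** Foreground is intensity ≥ the lower threshold. Manual
values reproduce user-chosen thresholds (per-image sidecar supported);
`otsu` maximizes between-class variance over all candidate splits of the
observed values. The threshold actually applied is recorded per image.

**Connectivity.** Foreground particles are 8-connected, background holes
4-connected (the standard digital-topology duality that stops holes leaking
through diagonals).

**Hole filling.** Background regions not 4-connected to the image border
become foreground; monotone and idempotent. A particle lying entirely
inside a hole of another is thereby absorbed — the enclosure rule used in
cluster counting.

**Watershed particle splitting.** The binary watershed computes the exact
Euclidean distance transform (EDT), seeds basins at its significant interior
peaks, and grows basins by priority flood on decreasing distance, committing
each pixel at pop time. Two numerical choices matter:

* *Seed detection uses the h-maxima transform (h = 2 px), not raw local
  maxima.* The EDT ridge of a digital shape ripples by more than a pixel
  (both its boundaries are jagged), so strict regional maxima shatter a
  single ring or lobe into many seeds. Reconstruction of EDT − h under the
  EDT levels every peak of prominence < h into one flat, connected plateau,
  while genuinely multi-lobed particles (a dumbbell's two discs, whose
  saddle is several pixels deep) keep distinct seeds. h = 2 px means: a lobe
  is split off only when the neck pinches by more than 2 px relative to the
  lobe radius — roughly the behaviour of ImageJ's integer-EDM watershed.
* Seeds closer than `min_seed_sep_px` (default 3) within one particle are
  merged; merging never crosses particles.

Every foreground pixel receives a label (no watershed lines), so the union
of labels equals the mask and particle areas are conserved.

**Endplate footprint.** The endplate territory is the rasterized convex
hull of the AChR pixel *centers* (`convex_hull`, default; exactly
idempotent — a corner-based hull would grow by a half-pixel band per
re-application) or morphological closing + hole fill (`close_fill`). Both
yield a single connected superset of the AChR mask, so compactness is
bounded by 100%.

**Endplate structure vs extraneous particles.** Real fields of view contain
debris and fragments of neighbouring endplates. The pipeline groups AChR
particles by dilation connectivity (edge-to-edge gap ≤ 2 × 10 px = 2 µm at
0.1 µm/px, configurable) and keeps the group with the largest stained area;
AChR measures and the footprint are computed on that restriction, and
cluster counting additionally requires each particle's centroid to lie in
the footprint. Consequence: adding particles far outside the endplate
changes no metric. This restriction is this package's resolution of an
inherent tension — a convex hull of *everything* would sweep distant debris
into the endplate.

**Cluster counting.** Each watershed particle is hole-filled and overlaid on
the footprint; a particle entirely inside another's hole is absorbed (one
biological cluster, not two), and particles outside the footprint are
excluded. This count is provably ≤ the raw watershed count. Average cluster
area = AChR area / count, so count × average = area exactly.

**Aberrant segmentation.** Segmentations resembling "spider webs" /
"broken windows" invalidate cluster counting. Headless QC flags an image
when more than `max_clusters` (50) particles lie in the footprint or the
median particle area falls below `min_cluster_area_um2` (0.25 µm²); flagged
images keep every non-cluster variable and record the reason. The
thresholds are this package's automation of what is, in interactive use, a
visual confirmation; they are deliberately conservative and configurable.

**Perimeter.** Chain-code length of Moore-traced contours through
boundary-pixel centers (1 per orthogonal, √2 per diagonal step), outer plus
hole contours; a 10 × 10 px square measures 36 px. Isolated single pixels
fall back to the unit square (4 px). Tiny particles are therefore slightly
underestimated relative to ImageJ's corner-polygon tracing — irrelevant at
endplate scale (hundreds of pixels across).

**Feret diameter.** Maximum caliper over the convex hull of pixel *corner*
coordinates (unit-square model, matching ImageJ's Feret on selections): a
single pixel measures √2 px.

**Skeleton statistics.** The terminal mask is thinned with Guo–Hall's
two-subiteration algorithm (textbook Zhang–Suen erodes 2-px-wide diagonal
strokes completely at some phase offsets — reproduced during development —
and would delete whole branches). Classification and lengths use the
*pruned skeleton graph*: 8-neighbour adjacency minus diagonal edges that
short-cut an orthogonal two-step path. In that graph, degree 1 = end point,
degree ≥ 3 = branch point (adjacent branch pixels merge into one junction);
terminal branches are the connected segments left after deleting branch
pixels, under the same pruned adjacency (plain 8-connectivity would fuse
the four arms of a one-pixel cross back together around the deleted
centre). Total branch length is the sum of pruned-graph edge weights;
spurs shorter than `prune_spurs_px` (default 2) that end in a tip are
discarded as thinning artifacts before counting.

**Axon.** Diameter comes from a user-supplied line (sidecar CSV, 0-based
row/col pixel coordinates), its Euclidean length × calibration; the erase
region is a polygon rasterized by the even-odd rule at pixel centers.
No automatic axon detection is attempted.

## Image I/O

Input is TIFF/OME-TIFF only; proprietary microscope formats must be
converted first. The package carries its own minimal baseline-TIFF codec
(uncompressed grayscale, multi-page, ImageJ-style hyperstack description,
channels interleaved fastest) because the target R stack has no TIFF
package; files round-trip with Fiji and Python tifffile (cross-checked in
the test suite). Calibration precedence is strict: file resolution
metadata, then an explicit config value, else an error naming the image —
all outputs are in µm/µm², so a guessed scale would corrupt every metric.

## The synthetic world

`generate_nmj()` renders fixtures with exhaustively known truth:

* AChR channel: discs and annuli at signal 220 on background 24 (8-bit),
  optionally one cluster fully enclosed in another's hole and extraneous
  particles far outside the endplate. A pixel is foreground iff its center
  lies inside the analytic shape (boundary inclusive).
* Nerve channel: a polyline tree stroked at width 3–5 px, plus an axon stub
  entering opposite the trunk; the stub stops clear of the root so the
  manual erase removes exactly the stub. In the randomized batch preset all
  segments lie on the 45° lattice, where an ideal digital line's chain
  length equals its Euclidean length, keeping length-recovery tolerances
  down to tip/junction terms.
* Noise: additive Gaussian (σ = 6 by default; 0 in the recovery batch),
  clipped to dtype; three z-slices with attenuation peaking at 1, so the
  maximum projection recovers the full-intensity image. Same seed, same
  bytes; the caller's RNG stream is left untouched.

`truth_metrics()` mixes closed forms (counts, πr² areas, polyline lengths,
the derived-variable formulas) with measurements on the *rasterized true
masks* (perimeters, Feret, footprint, contact) — a path that bypasses
noise, thresholding, watershed and thinning entirely. Each continuous
variable carries a per-fixture tolerance: 2% for raster-path and area
variables (areas also get a one-pixel-boundary-band floor), and for
skeleton lengths a geometric bound of (w/2 + 1) px per tip (cap erosion)
plus 2.5 w px per junction (two strokes diverging by 45° stay merged until
their lateral separation exceeds the width w, displacing the skeleton
junction by up to w/tan 22.5° ≈ 2.5 w).

What a green recovery run does establish: exact integer recovery (clusters,
branches, branch points) and sub-tolerance continuous recovery on clean,
well-separated geometry, and self-consistency of every derived variable.
What it does not: performance on real confocal data — no point-spread
blur, depth attenuation, anisotropic noise, touching endplates, or the
pretzel/nummular shape spectrum of real NMJs. The failure presets
(`spiderweb`, `low_quality`) only probe the QC contract, not recovery.

## Numerical choices, tie-breaks, degenerate inputs

* Otsu ties resolve to the lowest maximizing split; the applied value is
  recorded either way.
* Watershed pop order among equal distances is FIFO; partitions are
  deterministic, but a saddle band between equal basins is tie-break
  territory (the test suite demands ≥ 95% agreement with an independent
  ordered-growth oracle plus identical core labels, rather than pixel
  identity).
* Empty masks: thresholding warns (QC flag) rather than fails; measurement
  functions on empty masks error, and the pipeline records the affected
  variables as missing.
* Particles smaller than `min_particle_px` (4) are dropped as debris before
  any measurement.
* Complexity with a zero factor, fragmentation without clusters, and axon
  diameter without a line are all recorded as missing with QC flags, never
  as −Inf/0 stand-ins.

## Known limitations

* 2-D only: all measures are on projections; volumetric morphometry is out
  of scope.
* The aberrance heuristic is a proxy for expert eyes; its two thresholds
  were chosen conservatively, not fitted to data.
* Chain-code lengths overestimate oblique straight lines by up to 8%
  (the classic digital-geometry bias); branch lengths are therefore most
  comparable *within* a consistently processed dataset.
* The TIFF codec reads uncompressed baseline files only; compressed TIFFs
  must be re-saved.
* Counting axonal inputs (polyinnervation) and muscle fibre diameter are
  separate measurements outside this pipeline's scope.
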