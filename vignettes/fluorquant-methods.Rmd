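---
title: "Methods: probability-mask quantification of fluorescent signal area"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probability-mask quantification of fluorescent signal area}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorquant)
```

## The measurement problem

Fluorescence readouts of cell competition in the *Drosophila* optic lobe —
the *azot* fitness reporter, TUNEL staining of dying cells, and anti-Aβ42
antibody signal — are quantified as the **area of signal normalized to a
region of interest (ROI)**, the manually outlined optic lobe. Rather than
thresholding raw intensity (the classic ImageJ/Fiji workflow), the automated
workflow consumes a **pixel-classifier probability mask**: a per-pixel
likelihood, in [0, 1], that the pixel belongs to the signal of interest.
`fluorquant` implements everything downstream of the classifier:
post-processing of the probability mask into discrete signal objects,
ROI-normalized area and two-channel colocalization metrics, a
background-corrected intensity measure (CTCF), the walking-assay activity
metric, and the rank-based statistics used to compare groups.

## Segmentation model

A probability mask `P` is turned into signal objects in three steps:

1. **Binarize**: pixel is signal iff `P > t`. The per-signal thresholds are
   the published workflow's: `t = 0.05` for the green channels (TUNEL,
   anti-Aβ42) and `t = 0.1` for the *azot* reporter. The inequality is
   strict: a pixel exactly at the threshold is excluded. The thresholds are
   exclusion bounds ("unlikely to be signal"), and any fixed convention is
   equally defensible; strictness is the testable choice made here.
2. **Label**: maximal connected components of signal pixels, 8-connectivity
   by default (the ImageJ "Analyze Particles" adjacency, the baseline the
   automated method was validated against). Labels are assigned in raster
   order of each component's first pixel, so labeling is deterministic.
3. **Size-filter**: objects with pixel area **below** the per-signal minimum
   size are discarded — 17 px for TUNEL and *azot*, 18 px for the Aβ42
   antibody. "Minimum size" is read as the smallest admissible size: a 17-px
   object survives a 17-px minimum, a 16-px object does not.

Whether the probability threshold is applied per pixel or per object is not
decidable from the published description; both are implemented
(`probability_mode = "pixel"`, the default, and `"object_mean"`, which
binarizes at half the threshold and then drops objects whose *mean*
probability does not exceed it).

Segmentation runs on the full mask; the ROI only enters in quantification.
The size thresholds describe biological objects, not ROI-clipped fragments,
so clipping before filtering would bias the filter near the ROI boundary.

A reference segmenter (`intensity_segment_reference`) applies the identical
label-and-filter pipeline to raw intensity at a user threshold. It exists
solely as the "standard method" arm of the method-agreement harness
(`method_agreement`, `run_validation`), which pairs objects of two
segmentations by any-overlap matching. The matching is a maximum-cardinality
bipartite matching computed by augmenting paths, seeded in descending
overlap-area order with label-order tie-breaks: deterministic, and provably
equal to the brute-force maximum any-overlap pairing the tests check against.
(A pure greedy pass was considered and rejected: it can under-count matches
in chain configurations.)

## Quantification

* `area_fraction`: `area_percent = 100 × |signal ∩ ROI| / |ROI|`.
* `colocalize`: overlap area `|A ∩ B ∩ ROI|`, reported primarily as a
  percentage of ROI (the plotted quantity for *azot*–TUNEL double-positive
  cells). Per-object counts are secondary: in **partial** mode an A object
  counts as colocalized if it shares at least one ROI pixel with B; in
  **total** mode only if all its ROI pixels lie inside B. The published
  figures do not say which mode they used; partial is the default and both
  are exposed.
* `ctcf`: corrected total cell fluorescence,
  `CTCF = integrated density − cell area × mean background`, the standard
  control that a reporter's brightness is not driven by background. It is
  exactly invariant under adding a constant to every pixel.

## Locomotion

Walking-arena trajectories (time in s, centroid x/y in mm) yield the
**Activity Speed Threshold** metric: total time the interval speed is
strictly above 2.7 mm/s over the 5-minute assay. Interval speed is Euclidean
displacement between consecutive samples divided by the (possibly
nonuniform) time step. Flies immobile for **more than** 60 s are excluded:
any contiguous run of intervals with speed below a floor of 0.25 mm/s
(configurable; real centroids jitter, so exact zero would never trigger)
spanning strictly more than the window flags the fly. An optional centered
3-sample median filter (off by default) suppresses single-sample tracker
glitches; the published trajectory-analysis pipeline's internal smoothing is
unspecified, so no smoothing is the default.

## Statistics

Group data are not assumed Gaussian; results are summarized as median with a
95% CI and compared with the Kruskal–Wallis test plus Dunn's post hoc:

* `kruskal_wallis`: `H = 12/(N(N+1)) Σ nᵢ(R̄ᵢ − (N+1)/2)²` on pooled
  mid-ranks, divided by the tie correction `1 − Σ(t³−t)/(N³−N)`; p from
  χ²(k−1). All-identical data (tie factor 0) is a degenerate-data error, not
  a p-value.
* `dunn_posthoc`:
  `z = (R̄ᵢ − R̄ⱼ) / sqrt((N(N+1)/12 − Σ(t³−t)/(12(N−1)))(1/nᵢ + 1/nⱼ))`,
  two-sided normal p, adjusted over all k(k−1)/2 pairs. Default adjustment
  is Bonferroni (multiply by the number of pairs, cap at 1), mirroring the
  GraphPad convention under which the original analyses were run; Holm is
  available. Significance stars follow the published levels (\*
  p < 0.05 through \*\*\*\* p < 0.0001).
* `median_ci`: distribution-free CI from symmetric order statistics
  `(x₍ₗ₎, x₍ₙ₊₁₋ₗ₎)` with `l` the largest index whose binomial(n, ½) tail
  keeps coverage ≥ 95%. For n ≤ 5 the nominal level is unattainable; the
  sample range is returned and `achieved_coverage` (e.g. 0.9375 at n = 5)
  flags the shortfall rather than pretending.

## Synthetic ground truth

No raw images or tracks were released with the source study, so every claim
the test suite makes is grounded in a generator whose truth is exact:

* **Scenes** (`generate_scene`): disk-shaped objects per channel, placed by
  rejection sampling without intra-channel contact. Disks — not irregular
  blobs — because their rasterized pixel areas are exact and
  translation-invariant, which turns area and overlap oracles into integer
  identities. Inter-channel overlap for a designated channel pair is
  *engineered*: each paired object is placed at an integer offset chosen by
  exhaustive lattice search so its shared pixel count is as close as
  possible to `round(f × min(pair areas))`; all other inter-channel contact
  is forbidden, so total true overlap is the sum of the engineered pair
  overlaps. On a pixel grid intermediate fractions may be off by the lattice
  granularity; the ground truth therefore records the **realized** overlap
  (what a correct measurement must reproduce exactly), and the endpoints
  f = 0 and f = 1 are exact by construction. Probability maps set interior
  pixels to the channel's interior probability (default 1.0), background to
  iid Uniform(0, `noise_prob`) values, optionally followed by Gaussian blur.
  Defaults (128² frame, 10 disks of radius 4 per channel, interior
  probability 1, no noise) emulate the sparse puncta the published thresholds
  were tuned for.
* **What the generator does not emulate**: point-spread functions, chromatic
  shift, z-projection artifacts, tissue autofluorescence gradients,
  irregular cell shapes, touching cells, or hand-drawn ROI variability. A
  green test therefore establishes that the *measurement pipeline* is exact
  on its stated object model — not that the classifier upstream is good, nor
  that the thresholds are biologically optimal.
* **Trajectories** (`generate_trajectory`): piecewise-constant-speed tracks
  sampled at `dt` (default 0.1 s over 300 s). Segment lengths must be
  integer multiples of `dt` so sampled interval speeds equal the specified
  speeds and the analytic time-above-threshold is exact. Immobile runs are
  injected by forcing interval speed to zero.
* **Groups** (`generate_groups`): normal draws with per-group location
  shifts; zero shifts give the exchangeable null used to calibrate the
  Kruskal–Wallis type-I error by simulation.

## Numerical choices

* **Blur and the half-maximum threshold.** Gaussian blur of a binary object
  moves probability across the boundary symmetrically, so the level set at
  half the interior value is the area-preserving contour. The test
  exercising blurred scenes (σ = 0.5 px, background noise ceiling 0.01)
  therefore segments at threshold 0.5. The published thresholds (0.05/0.1)
  are near-zero exclusion bounds appropriate for the classifier's
  near-binary output; applied to a smoothly blurred edge they would dilate
  every object by about a pixel of perimeter, which is a property of the
  threshold, not an error of the pipeline.
* **Probability encodings.** 8-bit masks are divided by exactly 255, 16-bit
  by 65535; float masks must already lie in [0, 1] (values outside are an
  error, not silently clipped). The classifier's export depth is not stated
  in the source description, so both are first-class.
* **Rasterization.** Polygon ROIs include a pixel iff its center
  `(col + 0.5, row + 0.5)` is inside under the even–odd rule; centers
  exactly on an edge are included. Coordinates are 0-based, x = column,
  y = row, origin top-left — the ImageJ convention, so `.roi` files
  round-trip without shifts.
* **Exactness at thresholds.** Both the activity metric and binarization use
  strict `>`. Floating-point coordinates can round a speed that is
  mathematically equal to the threshold to either side; tests that pin the
  strictness convention therefore use dyadic-rational speeds and time steps,
  for which the sampled arithmetic is exact.
* **Result tables.** CSV with doubles printed at 17 significant digits, so
  re-reading reproduces every value bit-exactly and repeated runs are
  byte-identical. (The original workflow exported spreadsheets; a diffable
  text schema is the testable equivalent.)
* **Run configuration** is JSON (the schema is documented in
  `?read_run_config`), manifest-driven rather than directory-globbing, so a
  run is reproducible from text files alone.

## Known limitations

* The TIFF codec is deliberately minimal: uncompressed, grayscale,
  8/16-bit unsigned or 32-bit float, one sample per pixel (multi-channel
  data = one page or file per channel). Compressed or RGB TIFFs must be
  converted upstream.
* The Kruskal–Wallis p-value uses the χ² approximation; with fewer than ~3
  observations per group it is anticonservative, and no exact small-sample
  table is provided.
* The immobility exclusion implements "more than 1 min" as *any contiguous
  window*, not cumulative stillness; the source description is ambiguous,
  and the contiguous reading is the stricter, more common one.
* Which multiplicity adjustment the original Prism analysis applied is not
  stated; Bonferroni is the default here and Holm a flag away, and the two
  can disagree near significance boundaries.
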