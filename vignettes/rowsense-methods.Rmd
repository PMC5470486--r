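---
title: "Methods: optical plant detection and inter-plant spacing"
author: "rowsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical plant detection and inter-plant spacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowsense)
```

## The problem

Precision weeding and per-plant agrochemical application need the
along-track position of every crop plant in a row, to a few centimetres.
`rowsense` implements three ground-platform sensing chains that deliver
those positions relative to a ground-wheel encoder (the local odometric
reference, roughly 1 mm of travel per pulse), plus the metrics used to
score them, for rows of recently transplanted tomato plants (or wooden
calibration sticks) on a raised seedbed.

All along-track positions are in millimetres of encoder travel; `x` is the
travel direction, `y` the lateral direction, `z` up.

## Light-beam chain

A single infrared emitter/receiver pair crosses the row a few centimetres
above the bed, so only stems (not foliage) interrupt it. The receiver's
TTL state is sampled at every encoder pulse. Processing:

1. **Conversion.** Pulse counts become distance through the pulse distance
   relation (1.18 mm/pulse on the laboratory conveyor, 0.98 mm/pulse on
   the field wheel).
2. **Interval extraction.** Each maximal run of blocked samples becomes a
   detection with its start, end, length and mean in-run distance — the
   latter taken as the stem location. The interval length is the stem
   diameter estimate; quantization makes it an over-estimate by at most
   two pulse distances.
3. **Detection filter.** Intervals shorter than 4 mm along-track are
   dropped; they come from leaves, weeds and clods.
4. **Expected-distance merging.** Walking the detections in order, a
   candidate farther than the *expected plant distance* (the theoretical
   spacing plus a 20% margin) from the previous potential plant starts a
   new plant; a closer candidate is merged into it, the merged location
   being the contributing detection midpoint closest to the theoretical
   midpoint (previous plant location plus the theoretical spacing; a first
   plant uses its own seeding midpoint as the anchor).

Note that with a theoretical spacing of 100 mm the expected distance is
120 mm, so detections of *consecutive correctly spaced plants* merge: the
merge stage can only separate plants spaced beyond the expected distance.
For this reason the "fraction of stems detected" statistic is computed on
the filtered detections (each true stem matched one-to-one to a detection
within half the spacing), not on the merged plant records; merged records
keep their contributing detections so the two views stay consistent.

## Side-view LiDAR chain

A 2-D laser scanner (50 Hz, 0.5° resolution) looks at the row from the
side; each scan is a polar slice of the scene at one along-track position.

1. **Polar to Cartesian.** Ranges at or below 50 mm are discarded (that
   gate also removes no-return zeros); a beam `(r, α)` maps to
   `(0, r cos α, r sin α)` in the sensor frame (scan plane `x' = 0`).
2. **Pose + translation.** Points (as row vectors) are multiplied by the
   roll/pitch/yaw rotation matrices and translated along x by the encoder
   value of their scan. The side-view mounting is roll 0, pitch −180°,
   yaw 0, so `z = −z'` and each scan lands at `x = Enc`.
3. **Height normalization** subtracts the minimum z, and **manual seedbed
   delimitation** clips the cloud to the bed under study.
4. **Box-grid downsampling** (3-mm boxes, each occupied box replaced by
   its centroid) removes redundant returns.
5. **Ground removal.** In every along-track evaluation interval (80 mm for
   stick rows, 96 mm for tomato rows) a plane is fitted by MSAC: minimal
   samples of 3 points, hypotheses whose normal deviates more than 5° from
   vertical discarded, cost `Σ min(d², τ²)` with τ = 40 mm, 500 samples,
   then a least-squares refinement on the inliers. Inliers are removed as
   ground; the rest is the aerial (plant) cloud. Each interval stores its
   *ground line* — the plane cut at the median y of its inliers,
   `z = a x + b`.
6. **Clustering.** k-means (squared Euclidean, k-means++ seeding, five
   replicates keeping the lowest cost) on the 3-D aerial points, starting
   from `k₀ = floor(travelled/spacing + 1) × 2`. While any two centroids
   are closer along-track than 0.2 × the theoretical spacing, k is reduced
   by one and the clustering repeated. Clusters with fewer than 5 members
   are discarded.
7. **Three locations per cluster:** the centroid x (*centre of cluster*);
   the x of the lowest member (*lowest point*, ties to the smaller x); and
   the *stem/ground intersection*: the cluster's x values are binned at
   4 mm, the maximal-count bin kept (adjacent ties merged), members
   restricted to the bottom half of the cluster's z range, a line fitted
   through the survivors and intersected with the interval's ground line.

### Numerical choices

* **Cluster-count reduction warm start.** Lloyd iterations cannot move a
  centroid across the empty space between plants, so re-seeding from
  scratch at k−1 tends to split one plant vertically while merging two
  neighbours, and the reduction loop then overshoots. Each reduced round
  therefore warm-starts from the previous centroids with the
  along-track-closest pair merged (size-weighted), competing on cost with
  five fresh k-means++ replicates. The centroid-distance check itself is
  evaluated on the along-track coordinate: the minimum distance between
  plants is an along-track quantity, and a 3-D distance would never flag
  the vertical splits the loop exists to repair.
* **Stem line parameterization.** Stems are near-vertical and are cut by
  only one to three discrete scan planes, so regressing z on x is
  ill-conditioned (a tall column of points at nearly one x). The stem
  line is fitted as x on z — the same line, stably parameterized — and
  intersected with the ground line `z = a x + b`; an x-spread below 1 mm
  short-circuits to the median x. Fewer than two surviving stem points, a
  missing ground line, or a stem line parallel to the ground line fall
  back to the lowest point with a warning.
* **Trailing evaluation interval.** The last partial interval is folded
  into the preceding full one. A partial interval can contain a single
  scan — a set of collinear points with no admissible plane — which would
  otherwise leak an entire bed line into the aerial cloud.
* **Determinism.** MSAC sampling and k-means seeding draw from the RNG
  seeded by `lidar_config(seed=)`, so a pipeline run is reproducible.

## Image validation chain

A side-view camera fires every second; the encoder value at each frame
corresponds to the image centre. Plant pixels are segmented by green
dominance followed by erosion and morphological reconstruction; the stem
column is the median column of the bottom 20% of the largest component.
The displacement between consecutive frames (by default translational
registration of column-intensity profiles; a keypoint matcher can be
substituted, as the contract is only a signed pixel shift) divided into
the encoder distance gives the motion relation in mm/pixel. Each frame's
stem location is then

```
stem location = encoder value + offset_px × (mm per pixel)
```

with offsets positive toward larger along-track positions. Locations are
grouped into plants (a gap above half the theoretical spacing starts a
new plant) and averaged, with the per-plant standard deviation reported.

## Scoring

* `detection_accuracy(n_real, n_detected)` = 100 × min/max of the two
  counts — symmetric, so over- and under-detection are penalized alike;
  reported rounded to integers.
* `match_detections()` pairs estimates with true plants one-to-one under
  the half-spacing rule (an estimate farther than half the nominal spacing
  from every plant is a false positive). Among admissible matchings it
  maximizes the number of pairs, breaking ties by total absolute error.
  Because positions live on a line, an optimal matching is non-crossing
  and is found exactly by dynamic programming over the sorted sequences;
  a greedy nearest-first pairing was rejected because it is not
  maximum-cardinality in corner cases (two estimates can both be usable
  only in the crossed assignment).
* `summarize_error()` reports the mean and sample (n−1) standard deviation
  of the signed errors (estimate − truth, positive beyond the plant in the
  travel direction); a single pair reports a standard deviation of 0.
  Millimetre summaries are rounded to one decimal in reports.

## The synthetic row generator

`sim_config()` describes a simulated world: a raised seedbed (default
200 mm high, 400 mm wide, with a small along-track tilt so per-interval
plane fitting is non-trivial) carrying a row of plants at a nominal
spacing with Gaussian jitter, traversed at 360 mm/s. Plants are vertical
stem cylinders (195 × 10 mm by default) optionally topped by an
ellipsoidal foliage shell whose centre can lean along-track — the lean is
what makes the three LiDAR location methods disagree measurably. Sticks
are bare cylinders (250 × 12 mm by default; stick dimensions are a
package choice of realistic calibration stakes). Generators derive
independent RNG streams from one seed and emulate:

* `gen_beam_log()` — the beam state at every encoder pulse, blocked where
  the beam crosses a stem. The TTL state is held for one pulse on each
  side of the geometric interruption, so a stem of width w yields a run
  of length in `(w, w + 2 pulses]` — an 11.2-mm mean estimate for a 10-mm
  stem at 1.18 mm/pulse. Optional sub-4-mm blips emulate weeds.
* `gen_lidar_scans()` — per-scan ray casting against bed top, furrow
  floor, stems and foliage shells, with Gaussian range noise and
  pulse-quantized encoder values. Bed flank returns are not simulated
  (treated as absorbed); furrow returns are, and the recommended
  delimitation (`sim_lidar_config()`) insets the bed edges by 20 mm so
  range noise cannot smear furrow points across the bed boundary — the
  same judgement an operator makes when delimiting the bed by hand.
* `gen_frames()` — frame metadata with exact pinhole pixel offsets, and
  `render_frame()` draws green-on-textured-brown images whose content
  translates exactly with the encoder.

What the generator does **not** model: foliage occlusion between
neighbouring plants, wind motion, sunlight and radiometric effects,
encoder slip beyond quantization, vibration, and curved rows. Passing the
packaged tests therefore demonstrates the correctness of the processing
chains under controlled geometry, not field performance; field error
magnitudes reported elsewhere cannot be re-derived without the original
recordings.

## Reference conditions and problem sizes

`sim_preset()` pins the three study conditions used throughout the tests:
the laboratory light-beam row (11 plants, 100 ± 2 mm spacing,
1.18 mm/pulse), the field calibration stick row (19 sticks, 240 ± 10 mm,
range noise σ = 5 mm) and the field tomato rows (20 plants, 290 ± 30 mm,
σ = 5 mm). These sizes match the published row layouts (the tomato rows
are scaled from 51–55 plants to 20 to keep simulated clouds compact;
spacing, noise and geometry are unchanged). A full stick-row simulation
produces roughly 90 000 beams and runs through the pipeline in a few
seconds.

## Limitations

* The expected-distance merge cannot separate plants spaced within 1.2 ×
  the theoretical distance (see above); that is a property of the
  published procedure, preserved deliberately.
* The half-spacing matching radius makes "correct detection" dependent on
  the nominal spacing: the same estimates score differently on rows with
  different layouts.
* MSAC's 5° normal constraint assumes the platform is levelled to within
  a few degrees of the bed; steeper beds leave ground in the aerial cloud
  (by design, with a warning).
* The image chain assumes pure translational inter-frame motion; yawing
  platforms violate it and should plug in a keypoint-based shift
  estimator.
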