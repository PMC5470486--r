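# rowsense

Optical detection and along-track localization of individual crop plants
in a row, for precision weeding and per-plant agrochemical application.

Automated intra-row weeding needs every crop plant's position along the
row to a few centimetres. `rowsense` implements three complementary
sensing chains for ground platforms that carry a wheel encoder (~1 mm of
travel per pulse) as the local reference:

* **Light-beam + encoder** — a single infrared beam crossing the row at
  stem height; maximal blocked runs of the per-pulse TTL stream become
  detections with location = mean in-run distance, a 4-mm filter removes
  leaf/weed blips, and candidates are merged into plants whenever they
  fall within the *expected plant distance* (theoretical spacing + 20 %).
* **Side-view LiDAR** — 50-Hz, 0.5°-resolution scans are transformed into
  the platform frame by the row-vector pose chain
  `p = p' · Rx(φ) · Ry(θ) · Rz(ψ) · T(Enc)` (side view: φ=0, θ=−180°,
  ψ=0), height-normalized, clipped to the seedbed, downsampled on a 3-mm
  box grid, split into ground and aerial points by per-interval MSAC
  plane fits (τ = 40 mm, normals within 5° of vertical, cost
  Σ min(d², τ²)), clustered by k-means (k-means++, five replicates,
  k₀ = ⌊travelled/spacing + 1⌋ × 2) with a cluster-count reduction loop
  (no two centroids closer along-track than 0.2 × spacing, minimum
  cluster size 5), and finally localized three ways per cluster: centre
  of cluster, lowest point, and the intersection of the fitted stem line
  with the interval's ground line.
* **Image validation** — side-view frames every second; green-dominance
  segmentation with erosion + reconstruction finds the stem column, the
  inter-frame pixel shift against the encoder distance gives a motion
  relation (mm/pixel), and each frame contributes
  `stem location = encoder value + offset_px × mm_per_px`, averaged per
  plant.

Scoring uses the published conventions: the detection accuracy
`100 × min(n_real, n_detected) / max(n_real, n_detected)`, one-to-one
matching under the half-spacing false-positive rule (solved exactly by
dynamic programming), and mean ± sample standard deviation of signed
location errors. A synthetic row generator (seedbed, stems, foliage
shells, encoder, beam, LiDAR ray casting, camera frames) reproduces the
study conditions so every stage is testable without recordings.

## Worked example

Simulate the 19-stick calibration row (240-mm nominal spacing, 5-mm range
noise), run the full LiDAR pipeline, and score all three location
methods:

```r
library(rowsense)

sim    <- sim_preset("field_sticks", seed = 42)
truth  <- gen_row_truth(sim)
scans  <- gen_lidar_scans(truth, sim)
result <- run_lidar_pipeline(scans, sim_lidar_config(sim, seed = 42))
result
#> <lidar_result>
#>   n_raw: 90521
#>   n_range_gated: 34285
#>   n_delimited: 17855
#>   n_gridded: 17855
#>   n_aerial: 779
#>   travelled_mm: 4967.62
#>   initial_k: 42
#>   n_clusters: 19

build_run_report(result$estimates, truth, spacing = 240, seed = 42)
#> <run_report>
#>   cluster_centre: 19/19 detected, accuracy 100%, FP 0, FN 0
#>   lowest_point: 19/19 detected, accuracy 100%, FP 0, FN 0
#>   stem_ground_intersection: 19/19 detected, accuracy 100%, FP 0, FN 0

summarize_error(lidar_estimates(result, "cluster_centre"), truth, 240)
#> <error_summary> n = 19, mean 0.1 mm, std 1.2 mm
```

The diagnostics mirror the pipeline's reduction accounting: ~90 k raw
beams shrink to 34 k in-range points, 18 k above the seedbed, and 779
aerial (plant) points, which cluster into exactly the 19 sticks; every
stick is localized within a few millimetres by all three methods.

The same run is available from a shell via the installed CLI
(`inst/cli/rowsense`): `simulate`, `detect-beam`, `detect-lidar`,
`detect-image`, `evaluate`, `fixtures`.

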