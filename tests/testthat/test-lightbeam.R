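lab_cfg <- beam_config(1.18, 100)

test_that("pulse counts convert to millimetres", {
  expect_equal(pulses_to_mm(100, lab_cfg), 118)
  expect_equal(pulses_to_mm(0, lab_cfg), 0)
  expect_equal(pulses_to_mm(50, beam_config(0.98, 380)), 49)
  expect_error(pulses_to_mm(-1, lab_cfg), class = "rowsense_invalid_input")
})

test_that("beam config derives the expected distance with its 20% margin", {
  cfg <- beam_config(0.98, 380)
  expect_identical(cfg$expected_plant_distance, 380 * 1.2)
  expect_equal(cfg$detection_filter, 4)
  expect_error(beam_config(0, 100), class = "rowsense_invalid_input")
})

test_that("interval extraction finds maximal blocked runs", {
  cfg <- beam_config(1, 100)
  log <- beam_log(c(0, 10, 20, 30), c(0, 1, 1, 0))
  iv <- extract_intervals(log, cfg)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_mm, 10)
  expect_equal(iv$end_mm, 20)
  expect_equal(iv$length_mm, 10)
  expect_equal(iv$midpoint_mm, 15)

  expect_equal(nrow(extract_intervals(beam_log(0:20, rep(0, 21)), cfg)), 0)
  expect_equal(nrow(extract_intervals(beam_log(integer(0), integer(0)), cfg)), 0)
})

test_that("interval extraction matches a run-length-encoding oracle", {
  cfg <- beam_config(1.18, 100)
  set.seed(13)
  for (i in 1:20) {
    state <- sample(0:1, 200, replace = TRUE)
    log <- beam_log(0:199, state)
    iv <- extract_intervals(log, cfg)
    runs <- oracle_runs(state)
    expect_equal(nrow(iv), nrow(runs))
    d <- pulses_to_mm(0:199, cfg)
    expect_equal(iv$start_mm, d[runs$start])
    expect_equal(iv$end_mm, d[runs$end])
    expect_equal(iv$midpoint_mm,
                 mapply(function(a, b) mean(d[a:b]), runs$start, runs$end))
  }
})

test_that("short detections are filtered at the 4-mm threshold", {
  iv <- data.frame(start_mm = c(0, 50, 100), end_mm = c(3, 54, 112),
                   length_mm = c(3, 4, 12), midpoint_mm = c(1.5, 52, 106))
  out <- filter_short(iv, lab_cfg)
  expect_equal(out$length_mm, c(4, 12))
  expect_equal(nrow(filter_short(iv[0, ], lab_cfg)), 0)
})

test_that("lowering the detection filter never removes survivors", {
  set.seed(5)
  iv <- data.frame(start_mm = sort(runif(100, 0, 5000)))
  iv$length_mm <- rexp(100, 1 / 5)
  iv$end_mm <- iv$start_mm + iv$length_mm
  iv$midpoint_mm <- (iv$start_mm + iv$end_mm) / 2
  counts <- vapply(c(8, 6, 4, 2, 1, 0.5), function(f) {
    nrow(filter_short(iv, beam_config(1.18, 100, detection_filter = f)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[3], sum(iv$length_mm >= 4))
})

make_intervals <- function(midpoints, half = 5) {
  data.frame(start_mm = midpoints - half, end_mm = midpoints + half,
             length_mm = rep(2 * half, length(midpoints)),
             midpoint_mm = midpoints)
}

test_that("expected-distance merging follows the candidate evaluation rules", {
  cfg <- beam_config(1, 380)

  p <- merge_to_plants(make_intervals(c(0, 500)), cfg)
  expect_equal(p$location_mm, c(0, 500))
  expect_equal(p$distance_from_previous_mm, c(NA, 500))

  # 100 merges into plant 1 (100 <= 456) and the location moves to the
  # midpoint closest to the theoretical one (0 + 380); 450 is then within
  # the expected distance of the updated location and merges too
  p <- merge_to_plants(make_intervals(c(0, 100, 450)), cfg)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_intervals, 3)
  expect_equal(p$location_mm, 450)

  p <- merge_to_plants(make_intervals(770), cfg)
  expect_equal(p$location_mm, 770)
  expect_equal(nrow(merge_to_plants(make_intervals(numeric(0)), cfg)), 0)
})

test_that("merged plant locations stay within their contributing intervals", {
  cfg <- beam_config(1, 300)
  set.seed(9)
  for (i in 1:20) {
    mids <- sort(runif(sample(1:12, 1), 0, 4000))
    p <- merge_to_plants(make_intervals(mids), cfg)
    expect_lte(nrow(p), length(mids))
    members <- attr(p, "intervals")
    for (j in seq_len(nrow(p))) {
      iv <- make_intervals(mids)[members[[j]], ]
      expect_gte(p$location_mm[j], min(iv$start_mm))
      expect_lte(p$location_mm[j], max(iv$end_mm))
    }
    if (nrow(p) > 1) expect_true(all(p$distance_from_previous_mm[-1] > 0))
  }
})

test_that("the detection chain is translation-equivariant", {
  cfg <- beam_config(1, 380)
  sim <- sim_preset("field_sticks", seed = 4, spacing_mm = 500,
                    n_plants = 6, pulse_mm = 1)
  truth <- gen_row_truth(sim)
  log <- gen_beam_log(truth, sim)
  base <- detect_beam(log, cfg)$plants$location_mm
  shifted <- beam_log(log$pulse_count + 1000, log$beam_state)
  moved <- detect_beam(shifted, cfg)$plants$location_mm
  expect_equal(moved, base + 1000)
})

test_that("noise-free rows spaced beyond the expected distance are fully detected", {
  cfg <- beam_config(1.18, 300)
  sim <- sim_preset("lab_beam", seed = 2, n_plants = 9, spacing_mm = 380,
                    spacing_jitter_mm = 0)
  truth <- gen_row_truth(sim)
  det <- detect_beam(gen_beam_log(truth, sim), cfg)
  expect_equal(nrow(det$plants), length(truth$positions))
  expect_lte(nrow(det$plants), nrow(det$detections))
  err <- abs(det$plants$location_mm - truth$positions)
  expect_true(all(err <= cfg$pulse_distance_relation))
})

test_that("stem diameter estimates carry the quantization bound", {
  iv <- data.frame(start_mm = 100, end_mm = 111.2, length_mm = 11.2,
                   midpoint_mm = 105.6)
  expect_equal(estimate_diameter(iv), 11.2)
  expect_equal(estimate_diameter(make_intervals(50, half = 0)), 0)

  sim <- sim_preset("lab_beam", seed = 8, n_plants = 7, spacing_mm = 200)
  truth <- gen_row_truth(sim)
  det <- detect_beam(gen_beam_log(truth, sim), beam_config(1.18, 200))
  d <- estimate_diameter(det$detections)
  expect_true(all(d >= 10))
  expect_true(all(d <= 10 + 2 * 1.18))
})

test_that("reverse travel is rejected", {
  expect_error(beam_log(c(5, 3), c(0, 0)), class = "rowsense_invalid_input")
})
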