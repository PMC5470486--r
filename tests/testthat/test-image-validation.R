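# Synthetic frames: green structures on textured brown soil.

brown_field <- function(h = 120, w = 160, seed = 61) {
  set.seed(seed)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- 0.45 + matrix(runif(h * w, -0.05, 0.05), h, w)
  img[, , 2] <- 0.33 + matrix(runif(h * w, -0.05, 0.05), h, w)
  img[, , 3] <- 0.20 + matrix(runif(h * w, -0.05, 0.05), h, w)
  img
}

paint_disc <- function(img, row, col, radius, rgb = c(0.1, 0.5, 0.1)) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  disc <- (rr - row)^2 + (cc - col)^2 <= radius^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[disc] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

test_that("a green disc on soil is segmented to within its boundary", {
  img <- paint_disc(brown_field(), row = 40, col = 80, radius = 20)
  seg <- segment_plant(img)
  truth <- {
    rr <- matrix(seq_len(120), 120, 160)
    cc <- matrix(seq_len(160), 120, 160, byrow = TRUE)
    (rr - 40)^2 + (cc - 80)^2 <= 20^2
  }
  # mismatches confined to a 1-px erosion/rebuild boundary band
  band <- abs(sqrt((matrix(seq_len(120), 120, 160) - 40)^2 +
                   (matrix(seq_len(160), 120, 160, byrow = TRUE) - 80)^2) - 20) <= 1.5
  expect_true(all(seg$mask[!band] == truth[!band]))
  expect_equal(seg$stem_col, 80, tolerance = 2)
})

test_that("an all-soil image signals an empty mask", {
  expect_error(segment_plant(brown_field(seed = 62)),
               class = "rowsense_empty_mask")
})

test_that("erosion with rebuild removes small specks but keeps the plant", {
  img <- paint_disc(brown_field(), row = 50, col = 60, radius = 18)
  img <- paint_disc(img, row = 20, col = 130, radius = 1.2) # 3-px speck
  seg <- segment_plant(img, erode_radius = 2)
  expect_true(all(!seg$mask[1:30, 110:160]))
  expect_gt(seg$component_size, 800)
})

test_that("frame shift estimation recovers known translations", {
  truth <- row_truth(c(400, 700))
  cfg <- sim_config(n_plants = 2, seed = 1)
  f1 <- render_frame(truth, cfg, encoder_mm = 400, mm_per_px = 2)
  f2 <- render_frame(truth, cfg, encoder_mm = 400 + 37 * 2, mm_per_px = 2)
  expect_equal(estimate_shift(f1, f2), -37, tolerance = 1)
  expect_equal(estimate_shift(f1, f1), 0)
  set.seed(63)
  n1 <- array(runif(120 * 160 * 3), c(120, 160, 3))
  n2 <- array(runif(120 * 160 * 3), c(120, 160, 3))
  expect_error(estimate_shift(n1, n2), class = "rowsense_shift_failure")
})

test_that("the motion relation is encoder distance per pixel", {
  expect_equal(motion_relation(100, 50), 0.5)
  expect_equal(motion_relation(1, 1), 1)
  expect_equal(motion_relation(-40, 20), 0.5)
  expect_error(motion_relation(0, 10), class = "rowsense_no_motion")
})

test_that("the motion relation is constant along a constant-speed sequence", {
  truth <- row_truth(c(500, 800, 1100))
  cfg <- sim_config(n_plants = 3, seed = 2)
  enc <- seq(400, 1000, by = 120)
  frames <- lapply(enc, function(e) render_frame(truth, cfg, e, mm_per_px = 2))
  rel <- vapply(seq_len(length(enc) - 1), function(i) {
    motion_relation(estimate_shift(frames[[i]], frames[[i + 1]]),
                    enc[i + 1] - enc[i])
  }, numeric(1))
  expect_equal(rel, rep(2, length(rel)), tolerance = 0.05)
})

test_that("stem locations follow the signed-offset relation", {
  expect_equal(stem_location(1000, 0, 0.5), 1000)
  expect_equal(stem_location(1000, 40, 0.5), 1020)
  expect_equal(stem_location(1000, -40, 0.5), 980)
  expect_error(stem_location(1000, 10, 0), class = "rowsense_invalid_input")
})

test_that("per-frame locations of one plant are identical under exact motion", {
  cfg <- sim_config(n_plants = 4, spacing_mm = 300, spacing_jitter_mm = 5,
                    seed = 64)
  truth <- gen_row_truth(cfg)
  frames <- gen_frames(truth, cfg)
  obs <- frames[!is.na(frames$stem_offset_px), ]
  loc <- stem_location(obs$encoder_mm, obs$stem_offset_px, cfg$mm_per_px)
  for (xp in truth$positions) {
    mine <- loc[abs(loc - xp) < 1e-6]
    expect_gte(length(mine), 1)
    expect_equal(mine, rep(xp, length(mine)))
  }
})

test_that("plant grouping averages per-frame locations", {
  frames <- data.frame(encoder_mm = c(990, 1000, 1010),
                       stem_offset_px = c(20, 4, -24))
  out <- locate_plants_from_frames(frames, 0.5, 300)
  expect_equal(nrow(out), 1)
  expect_equal(out$location_mm, mean(c(1000, 1002, 998)))
  expect_equal(out$std_mm, 2)
  expect_equal(out$n_frames, 3)

  one <- locate_plants_from_frames(
    data.frame(encoder_mm = 500, stem_offset_px = 10), 1, 300)
  expect_equal(one$location_mm, 510)
  expect_equal(one$std_mm, 0)

  two <- locate_plants_from_frames(
    data.frame(encoder_mm = c(1000, 1000), stem_offset_px = c(-150, 150)),
    1, 290)
  expect_equal(nrow(two), 2)

  none <- locate_plants_from_frames(
    data.frame(encoder_mm = 100, stem_offset_px = NA), 1, 300)
  expect_equal(nrow(none), 0)
})

test_that("averaging stays inside the per-frame location range", {
  set.seed(65)
  for (i in 1:10) {
    enc <- sort(runif(6, 0, 400))
    frames <- data.frame(encoder_mm = enc,
                         stem_offset_px = rnorm(6, 0, 30))
    loc <- stem_location(frames$encoder_mm, frames$stem_offset_px, 0.5)
    out <- locate_plants_from_frames(frames, 0.5, 4000)
    expect_equal(nrow(out), 1)
    expect_gte(out$location_mm, min(loc))
    expect_lte(out$location_mm, max(loc))
  }
})

test_that("end-to-end frame spacing recovery is within two pixels", {
  cfg <- sim_config(n_plants = 6, spacing_mm = 300, spacing_jitter_mm = 10,
                    seed = 66)
  truth <- gen_row_truth(cfg)
  plants <- locate_plants_from_frames(gen_frames(truth, cfg),
                                      cfg$mm_per_px, cfg$spacing_mm)
  expect_equal(nrow(plants), 6)
  est_sp <- spacing_series(plants$location_mm)
  true_sp <- spacing_series(truth$positions)
  expect_true(all(abs(est_sp - true_sp) <= 2 * cfg$mm_per_px))
})
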