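test_that("detection accuracy reproduces the field detection ratios", {
  cases <- list(c(32, 41, 78), c(34, 32, 94), c(48, 49, 98), c(10, 10, 100))
  for (cs in cases) {
    expect_equal(round(detection_accuracy(cs[1], cs[2])), cs[3])
  }
  expect_error(detection_accuracy(0, 5), class = "rowsense_invalid_input")
})

test_that("detection accuracy is symmetric and bounded", {
  set.seed(11)
  for (i in 1:50) {
    a <- sample(1:200, 1); b <- sample(1:200, 1)
    expect_equal(detection_accuracy(a, b), detection_accuracy(b, a))
    expect_gt(detection_accuracy(a, b), 0)
    expect_lte(detection_accuracy(a, b), 100)
  }
})

test_that("detection rate recovers the correct-detection percentage", {
  rep <- match_detections(c(10, 310), row_truth(c(0, 300, 600)), 300)
  expect_equal(detection_rate(rep), 100 * 2 / 3)
  expect_equal(round(detection_rate(53, 2)), 96)
})

test_that("matching follows the half-spacing rule on worked examples", {
  r <- match_detections(c(10, 310, 590), row_truth(c(0, 300, 600)), 300)
  expect_equal(r$n_correct, 3)
  expect_equal(r$n_false_positive, 0)
  expect_equal(r$n_false_negative, 0)

  # 460 can only pair with 600 (|460 - 600| = 140 <= 150)
  r <- match_detections(c(10, 460), row_truth(c(0, 300, 600)), 300)
  expect_equal(r$n_correct, 2)
  expect_equal(r$n_false_negative, 1)
  expect_setequal(r$pairs$truth_index, c(1, 3))

  r <- match_detections(numeric(0), row_truth(c(0, 300, 600)), 300)
  expect_equal(unlist(r[c("n_correct", "n_false_positive", "n_false_negative")]),
               c(n_correct = 0, n_false_positive = 0, n_false_negative = 3))

  r <- match_detections(c(5, 900), numeric(0), 300)
  expect_equal(r$n_false_positive, 2)
})

test_that("matching equals the exhaustive oracle and keeps count identities", {
  set.seed(7)
  for (i in 1:60) {
    nt <- sample(0:8, 1); ne <- sample(0:8, 1)
    truth <- sort(runif(nt, 0, 2000))
    est <- runif(ne, -100, 2100)
    spacing <- runif(1, 50, 400)
    r <- match_detections(est, truth, spacing)
    expect_equal(r$n_correct + r$n_false_negative, nt)
    expect_equal(r$n_correct + r$n_false_positive, ne)
    expect_true(all(r$pairs$abs_error_mm <= spacing / 2))
    oracle <- oracle_match(est, truth, spacing / 2)
    expect_equal(r$n_correct, oracle[1])
    expect_equal(sum(r$pairs$abs_error_mm), oracle[2], tolerance = 1e-9)
  }
})

test_that("matching resists the greedy counterexample", {
  # greedy-by-smallest-error would pair 40 with 30 and leave 0 stranded;
  # the optimal assignment pairs (40, 85) and (0, 30)
  r <- match_detections(c(40, 0), row_truth(c(30, 85)), 100)
  expect_equal(r$n_correct, 2)
})

test_that("spacing series equals element-wise differences", {
  expect_equal(spacing_series(c(0, 100, 200)), c(100, 100))
  expect_equal(spacing_series(c(0, 102.5, 205.0)), c(102.5, 102.5))
  expect_length(spacing_series(5), 0)
  set.seed(3)
  v <- sort(runif(40, 0, 5000))
  expect_equal(spacing_series(v), v[-1] - v[-length(v)])
})

test_that("error summary uses signed errors with the sample convention", {
  s <- summarize_error(c(0, 300), row_truth(c(0, 300)), 300)
  expect_equal(s$mean_mm, 0)
  expect_equal(s$std_mm, 0)

  s <- summarize_error(c(10, 290), row_truth(c(0, 300)), 300)
  expect_equal(s$mean_mm, 0)
  expect_equal(s$std_mm, 10 * sqrt(2), tolerance = 1e-9)

  expect_error(summarize_error(c(5000), row_truth(c(0)), 300),
               class = "rowsense_no_matches")
})

test_that("error summary recovers a known error distribution", {
  set.seed(21)
  n <- 1000
  truth <- row_truth(seq(0, by = 1000, length.out = n))
  err <- rnorm(n, mean = 12, sd = 30)
  s <- summarize_error(truth$positions + err, truth, 1000)
  expect_equal(s$n, n)
  expect_lt(abs(s$mean_mm - 12), 3 * 30 / sqrt(n))
  expect_lt(abs(s$std_mm - 30), 3 * 30 / sqrt(2 * n))
})

test_that("row truth validates its invariants", {
  expect_error(row_truth(c(10, 5)), class = "rowsense_invalid_input")
  expect_error(row_truth(c(-5, 10)), class = "rowsense_invalid_input")
  expect_error(row_truth(c(5, 5)), class = "rowsense_invalid_input")
  expect_silent(row_truth(numeric(0)))
})

test_that("plant estimates validate method and location", {
  e <- plant_estimate(c(10, 20), "beam")
  expect_s3_class(e, "plant_estimate")
  expect_error(plant_estimate(10, "teleport"))
  expect_error(plant_estimate(-4, "beam"), class = "rowsense_invalid_input")
})
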