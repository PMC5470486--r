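lcfg <- lidar_config(290)

test_that("the initial cluster count follows the floor formula", {
  expect_equal(initial_k(10000, 290), 70L)
  expect_equal(initial_k(240, 240), 4L)
  expect_equal(initial_k(100, 240), 2L)
  expect_error(initial_k(0, 240), class = "rowsense_invalid_input")
})

test_that("two well-separated blobs reduce to exactly two clusters", {
  set.seed(51)
  aerial <- rbind(blob(40, c(500, 0, 100)), blob(40, c(1000, 0, 100)))
  cl <- cluster_plants(aerial, 6, lcfg)
  expect_length(cl, 2)
  cx <- sort(vapply(cl, function(c) c$centroid[1], numeric(1)))
  expect_equal(cx, c(500, 1000), tolerance = 0.02)

  cl <- cluster_plants(blob(50, c(700, 0, 120)), 4, lcfg)
  expect_length(cl, 1)
})

test_that("clusters below the minimum size are excluded", {
  set.seed(52)
  aerial <- rbind(blob(30, c(500, 0, 100), sd = 5),
                  matrix(rep(c(1100, 0, 100), each = 4), ncol = 3) +
                    matrix(rnorm(12, 0, 1), ncol = 3))
  cl <- cluster_plants(aerial, 4, lcfg)
  expect_length(cl, 1)
  expect_gte(cl[[1]]$size, 5)
})

test_that("no centroid pair survives closer than the minimum plant distance", {
  set.seed(53)
  for (i in 1:8) {
    n_blobs <- sample(2:6, 1)
    centres <- cumsum(runif(n_blobs, 150, 500))
    aerial <- do.call(rbind, lapply(centres, function(cx) {
      blob(sample(10:40, 1), c(cx, rnorm(1, 0, 20), runif(1, 50, 250)), sd = 12)
    }))
    cl <- cluster_plants(aerial, initial_k(diff(range(aerial[, 1])) + 300, 290), lcfg)
    cx <- sort(vapply(cl, function(c) c$centroid[1], numeric(1)))
    if (length(cx) > 1) {
      expect_true(all(diff(cx) >= lcfg$min_distance_between_plants))
    }
  }
})

test_that("the centre method returns the centroid x", {
  set.seed(54)
  sym <- expand.grid(x = 990:1010, y = -5:5, z = c(50, 100))
  cl <- make_cluster(as.matrix(sym))
  expect_equal(locate_centre(cl), 1000)
  expect_equal(locate_centre(make_cluster(rbind(c(432, 1, 2)))), 432)
  pts <- blob(60, c(700, 0, 100))
  expect_equal(locate_centre(make_cluster(pts)), mean(pts[, 1]))
})

test_that("the lowest-point method takes the minimum z with x tie-break", {
  pts <- rbind(c(1005, 0, 50), c(995, 0, 10), c(1000, 0, 200))
  expect_equal(locate_lowest(make_cluster(pts)), 995)
  ties <- rbind(c(1010, 0, 10), c(990, 0, 10), c(1000, 0, 50))
  expect_equal(locate_lowest(make_cluster(ties)), 990)
  set.seed(55)
  pts <- blob(80, c(600, 0, 150), sd = 20)
  expect_equal(locate_lowest(make_cluster(pts)), pts[which.min(pts[, 3]), 1])
})

test_that("a vertical stem intersects flat ground at its own x", {
  set.seed(56)
  stem <- cbind(1000 + runif(40, -0.4, 0.4), rnorm(40, 0, 3),
                seq(5, 200, length.out = 40))
  x <- locate_stem_intersection(make_cluster(stem), flat_ground_model(), lcfg)
  expect_lt(abs(x - 1000), lcfg$grid_step_mm)
})

test_that("a leaning plant's stem intersection recovers the base, not the canopy", {
  set.seed(57)
  # stem rises from x = 1000 with slope 0.1 mm/mm; canopy sits 50 mm beyond
  stem <- cbind(1000 + 0.1 * seq(0, 150, length.out = 60) + runif(60, -1, 1),
                rnorm(60, 0, 3), seq(0, 150, length.out = 60))
  canopy <- blob(90, c(1050, 0, 230), sd = 25)
  cl <- make_cluster(rbind(stem, canopy))
  xi <- locate_stem_intersection(cl, flat_ground_model(), lcfg)
  xc <- locate_centre(cl)
  expect_lt(abs(xi - 1000), 10)
  expect_gt(xc - xi, 25) # the centre sits toward the canopy
})

test_that("all three locations agree on a cylindrical stick", {
  set.seed(58)
  stick <- cbind(800 + runif(60, -2, 2), rnorm(60, 0, 2),
                 runif(60, 5, 250))
  cl <- make_cluster(stick)
  xs <- c(locate_centre(cl), locate_lowest(cl),
          locate_stem_intersection(cl, flat_ground_model(), lcfg))
  expect_lt(diff(range(xs)), 2 * lcfg$grid_step_mm)
})

test_that("degenerate stem fits fall back to the lowest point with a warning", {
  pts <- rbind(c(1000, 0, 10), c(1004, 0, 10), c(990, 0, 300),
               c(991, 0, 300), c(992, 0, 301))
  expect_warning(
    x <- locate_stem_intersection(make_cluster(pts),
                                  flat_ground_model()[0, ], lcfg),
    "fell back"
  )
  expect_equal(x, locate_lowest(make_cluster(pts)))
})
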