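# Independent brute-force oracles used to freeze expected values.

# Exhaustive one-to-one matching: maximize the number of pairs within
# `radius`, break ties by minimum total |error|. Returns c(count, cost).
oracle_match <- function(estimates, truth, radius) {
  n_t <- length(truth)
  best <- c(0, 0)
  recurse <- function(ti, used, count, cost) {
    if (ti > n_t) {
      if (count > best[1] || (count == best[1] && cost < best[2])) {
        best <<- c(count, cost)
      }
      return(invisible())
    }
    recurse(ti + 1, used, count, cost) # leave this truth unmatched
    for (ei in seq_along(estimates)) {
      if (!used[ei] && abs(estimates[ei] - truth[ti]) <= radius) {
        used2 <- used
        used2[ei] <- TRUE
        recurse(ti + 1, used2, count + 1, cost + abs(estimates[ei] - truth[ti]))
      }
    }
  }
  recurse(1, rep(FALSE, length(estimates)), 0, 0)
  best
}

# Run-length-encoding oracle for beam interval extraction.
oracle_runs <- function(state) {
  r <- rle(as.integer(state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values == 1], end = ends[r$values == 1])
}

# Hash-grid oracle for box-grid downsampling, written independently of the
# implementation (explicit loop over occupied cells).
oracle_grid <- function(cloud, step) {
  anchor <- apply(cloud, 2, min)
  cell <- floor(t((t(cloud) - anchor) / step))
  keys <- apply(cell, 1, paste, collapse = "/")
  t(vapply(unique(keys), function(k) {
    colMeans(cloud[keys == k, , drop = FALSE])
  }, numeric(3)))
}

# Small deterministic cluster fixture: a Gaussian blob.
blob <- function(n, centre, sd = 8) {
  cbind(rnorm(n, centre[1], sd), rnorm(n, centre[2], sd), rnorm(n, centre[3], sd))
}

make_cluster <- function(points) {
  list(id = 1L, points = points, centroid = colMeans(points),
       size = nrow(points))
}

flat_ground_model <- function(x_min = -1e6, x_max = 1e6, a = 0, b = 0) {
  gm <- data.frame(x_min = x_min, x_max = x_max, nx = 0, ny = 0, nz = 1,
                   offset = b, line_a = a, line_b = b, n_ground = 100L)
  class(gm) <- c("ground_model", "data.frame")
  gm
}
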