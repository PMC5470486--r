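# MSAC (M-estimator SAmple Consensus) plane fitting with an orientation
# constraint, and per-interval ground removal.

# Fit one plane to a point set. Minimal sample of 3 points; hypotheses whose
# normal deviates from the reference direction by more than the angular
# constraint are discarded before scoring; cost is the truncated squared
# distance sum(min(d^2, tau^2)). The winning hypothesis is refined by a
# least-squares fit (PCA) on its inliers, kept only if the refined normal
# still satisfies the constraint. Returns NULL when no admissible plane is
# found. Uses the current RNG stream.
fit_plane_msac <- function(points, threshold, reference_vector = c(0, 0, 1),
                           max_angle_deg = 5, iterations = 500) {
  points <- as_cloud(points)
  n <- nrow(points)
  if (n < 3) return(NULL)
  ref <- reference_vector / sqrt(sum(reference_vector^2))
  cos_max <- cospi(max_angle_deg / 180)
  tau2 <- threshold^2

  best_cost <- Inf
  best <- NULL
  for (it in seq_len(iterations)) {
    s <- sample.int(n, 3)
    p1 <- points[s[1], ]; p2 <- points[s[2], ]; p3 <- points[s[3], ]
    u <- p2 - p1; v <- p3 - p1
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-9) next
    nrm <- nrm / len
    if (abs(sum(nrm * ref)) < cos_max) next  # orientation constraint
    if (sum(nrm * ref) < 0) nrm <- -nrm
    offset <- sum(nrm * p1)
    d2 <- (points %*% nrm - offset)^2
    cost <- sum(pmin(d2, tau2))
    if (cost < best_cost) {
      best_cost <- cost
      best <- list(normal = nrm, offset = offset)
    }
  }
  if (is.null(best)) return(NULL)

  # least-squares refinement on the inliers of the winning hypothesis
  d <- abs(points %*% best$normal - best$offset)
  inl <- d <= threshold
  if (sum(inl) >= 3) {
    sub <- points[inl, , drop = FALSE]
    ctr <- colMeans(sub)
    ev <- eigen(stats::cov(sub), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    if (abs(sum(nrm * ref)) >= cos_max) {
      if (sum(nrm * ref) < 0) nrm <- -nrm
      best <- list(normal = nrm, offset = sum(nrm * ctr))
    }
  }
  d <- abs(points %*% best$normal - best$offset)
  best$inliers <- as.vector(d <= threshold)
  best
}

#' Separate aerial (plant) points from the ground
#'
#' Walks the cloud in along-track evaluation intervals; in each interval a
#' plane constrained to be near-horizontal is fitted by MSAC and its inliers
#' (points within the distance threshold) are labelled ground and removed.
#' The union of the non-inliers over all intervals is the aerial cloud.
#' Intervals with fewer than three points, or where no admissible plane
#' exists (e.g. the local surface is tilted beyond the angular constraint),
#' contribute all their points to the aerial cloud with a warning.
#'
#' Each interval also stores its ground line: the fitted plane intersected
#' with the vertical plane y = median(y of the ground inliers), expressed as
#' z = a x + b. The stem-line location method intersects stem lines with
#' these.
#'
#' @param cloud n x 3 matrix (platform frame, heights normalized).
#' @param config A [lidar_config()].
#' @return A list of class `aerial_extraction`: `aerial` (matrix),
#'   `ground_model` (data.frame of class `ground_model` with one row per
#'   interval: `x_min`, `x_max`, `nx`, `ny`, `nz`, `offset`, `line_a`,
#'   `line_b`, `n_ground`), and `n_ground` (total ground points removed).
#' @export
extract_aerial <- function(cloud, config) {
  cloud <- as_cloud(cloud)
  gm <- data.frame(x_min = numeric(0), x_max = numeric(0),
                   nx = numeric(0), ny = numeric(0), nz = numeric(0),
                   offset = numeric(0), line_a = numeric(0),
                   line_b = numeric(0), n_ground = integer(0))
  class(gm) <- c("ground_model", "data.frame")
  if (nrow(cloud) == 0) {
    return(structure(list(aerial = cloud, ground_model = gm, n_ground = 0L),
                     class = "aerial_extraction"))
  }

  step <- config$eval_interval_mm
  x0 <- min(cloud[, 1])
  # the trailing partial interval is folded into the last full one so no
  # interval degenerates to a single scan line
  nbins <- max(1, floor((max(cloud[, 1]) - x0) / step))
  bin <- pmin(floor((cloud[, 1] - x0) / step), nbins - 1)
  aerial_keep <- rep(TRUE, nrow(cloud))
  skipped <- 0L
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    if (length(idx) < 3) {
      skipped <- skipped + 1L
      next
    }
    fit <- fit_plane_msac(cloud[idx, , drop = FALSE],
                          threshold = config$msac_threshold_mm,
                          reference_vector = config$reference_vector,
                          max_angle_deg = config$max_angular_distance_deg,
                          iterations = config$msac_iterations)
    if (is.null(fit)) {
      skipped <- skipped + 1L
      next
    }
    aerial_keep[idx[fit$inliers]] <- FALSE
    y0 <- stats::median(cloud[idx[fit$inliers], 2])
    nrm <- fit$normal
    gm[nrow(gm) + 1L, ] <- list(x0 + b * step, x0 + (b + 1) * step,
                                nrm[1], nrm[2], nrm[3], fit$offset,
                                -nrm[1] / nrm[3],
                                (fit$offset - nrm[2] * y0) / nrm[3],
                                sum(fit$inliers))
  }
  if (skipped > 0) {
    warning(sprintf(
      "%d evaluation interval(s) had no admissible ground plane; their points pass through as aerial",
      skipped), call. = FALSE)
  }
  structure(
    list(aerial = cloud[aerial_keep, , drop = FALSE],
         ground_model = gm,
         n_ground = sum(!aerial_keep)),
    class = "aerial_extraction"
  )
}

# Ground line (a, b) applicable at along-track position x: the interval
# containing x, else the nearest interval; NULL when no ground was fitted.
ground_line_at <- function(ground_model, x) {
  if (nrow(ground_model) == 0) return(NULL)
  hit <- which(x >= ground_model$x_min & x <= ground_model$x_max)
  i <- if (length(hit)) hit[1] else {
    which.min(pmin(abs(ground_model$x_min - x), abs(ground_model$x_max - x)))
  }
  list(a = ground_model$line_a[i], b = ground_model$line_b[i])
}
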