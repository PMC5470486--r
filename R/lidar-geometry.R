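#' LiDAR scan set
#'
#' Long-format container for side-view LiDAR scans: one row per beam, with
#' the scan id, timestamp, the encoder value recorded at the scan (mm), the
#' beam angle (degrees, 0.5-degree steps) and the measured range (mm).
#' A range of 0 encodes "no return".
#'
#' @param scan_id Integer scan index, non-decreasing.
#' @param timestamp_ms Scan timestamps (ms).
#' @param encoder_mm Encoder value at each scan (mm), non-decreasing
#'   across scans.
#' @param angle_deg Beam angle within the scan plane (degrees), strictly
#'   increasing within each scan.
#' @param range_mm Measured range (mm), >= 0.
#' @return A data.frame of class `scan_set`.
#' @export
scan_set <- function(scan_id, timestamp_ms, encoder_mm, angle_deg, range_mm) {
  out <- data.frame(scan_id = as.integer(scan_id),
                    timestamp_ms = timestamp_ms,
                    encoder_mm = encoder_mm,
                    angle_deg = angle_deg,
                    range_mm = range_mm)
  if (nrow(out)) {
    if (any(out$range_mm < 0)) rs_invalid("ranges must be >= 0")
    enc <- tapply(out$encoder_mm, out$scan_id, `[`, 1)
    if (any(diff(enc[order(as.integer(names(enc)))]) < 0)) {
      rs_invalid("encoder values must be non-decreasing across scans")
    }
    bad <- tapply(out$angle_deg, out$scan_id, function(a) any(diff(a) <= 0))
    if (any(unlist(bad))) {
      rs_invalid("angles must be strictly increasing within a scan")
    }
  }
  class(out) <- c("scan_set", "data.frame")
  out
}

#' Sensor pose and along-track translation
#'
#' Roll / pitch / yaw (degrees, about x / y / z) plus the encoder-derived
#' x translation applied when mapping sensor coordinates to the platform
#' frame. The side-view mounting uses (0, -180, 0, Enc_t).
#'
#' @param roll_deg,pitch_deg,yaw_deg Rotation angles in degrees, each
#'   within \[-360, 360\].
#' @param x_translation_mm Along-track translation (the encoder value).
#' @return An object of class `pose`.
#' @export
pose <- function(roll_deg = 0, pitch_deg = 0, yaw_deg = 0, x_translation_mm = 0) {
  ang <- c(roll_deg, pitch_deg, yaw_deg)
  if (any(!is.finite(ang)) || any(abs(ang) > 360)) {
    rs_invalid("pose angles must lie in [-360, 360]")
  }
  structure(list(roll_deg = roll_deg, pitch_deg = pitch_deg, yaw_deg = yaw_deg,
                 x_translation_mm = x_translation_mm),
            class = "pose")
}

# Homogeneous transformation for row-vector points: p_platform = p_sensor %*% M.
# The rotation matrices are written exactly in the row-vector convention of
# the platform calibration (note the sign placements); cospi/sinpi keep the
# multiples of 90 degrees exact.
pose_matrix <- function(pose) {
  cr <- cospi(pose$roll_deg / 180);  sr <- sinpi(pose$roll_deg / 180)
  cp <- cospi(pose$pitch_deg / 180); sp <- sinpi(pose$pitch_deg / 180)
  cy <- cospi(pose$yaw_deg / 180);   sy <- sinpi(pose$yaw_deg / 180)
  rx <- rbind(c(1, 0, 0, 0),
              c(0, cr, sr, 0),
              c(0, -sr, cr, 0),
              c(0, 0, 0, 1))
  ry <- rbind(c(cp, 0, -sp, 0),
              c(0, 1, 0, 0),
              c(sp, 0, cp, 0),
              c(0, 0, 0, 1))
  rz <- rbind(c(cy, sy, 0, 0),
              c(-sy, cy, 0, 0),
              c(0, 0, 1, 0),
              c(0, 0, 0, 1))
  tr <- rbind(c(1, 0, 0, 0),
              c(0, 1, 0, 0),
              c(0, 0, 1, 0),
              c(pose$x_translation_mm, 0, 0, 1))
  rx %*% ry %*% rz %*% tr
}

#' Convert one polar scan to Cartesian sensor-frame points
#'
#' Applies the range gate (returns at or below `min_range_mm` are dropped,
#' which also removes "no return" zeros) and maps each surviving beam
#' `(r, alpha)` to `(0, r cos(alpha), r sin(alpha))`: the scan plane is
#' x' = 0, alpha = 0 points along +y', and positive alpha rotates toward
#' +z'.
#'
#' @param angle_deg Beam angles (degrees).
#' @param range_mm Ranges (mm), same length.
#' @param config A [lidar_config()].
#' @return An n x 3 matrix of sensor-frame points (possibly 0 rows).
#' @export
polar_to_cartesian <- function(angle_deg, range_mm, config) {
  keep <- range_mm > config$min_range_mm
  r <- range_mm[keep]
  a <- angle_deg[keep]
  cbind(x = rep(0, length(r)),
        y = r * cospi(a / 180),
        z = r * sinpi(a / 180))
}

#' Transform sensor-frame points into the platform frame
#'
#' Each point, as a row vector, is multiplied by the roll, pitch and yaw
#' rotation matrices in that order, then translated along x by the encoder
#' value. With zero angles and zero translation this is the identity; any
#' pose with zero translation is an isometry.
#'
#' @param cloud n x 3 matrix of points (mm).
#' @param pose A [pose()].
#' @return n x 3 matrix in the platform frame (x = travel direction,
#'   z = up).
#' @export
apply_pose <- function(cloud, pose) {
  cloud <- as_cloud(cloud)
  if (nrow(cloud) == 0) return(cloud)
  m <- pose_matrix(pose)
  out <- cbind(cloud, 1) %*% m
  out <- out[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

as_cloud <- function(cloud) {
  cloud <- as.matrix(cloud)
  if (length(cloud) == 0) {
    cloud <- matrix(numeric(0), ncol = 3)
  }
  if (ncol(cloud) != 3) rs_invalid("a point cloud must have 3 columns")
  if (any(!is.finite(cloud))) rs_invalid("point coordinates must be finite")
  colnames(cloud) <- c("x", "y", "z")
  cloud
}

#' Rebase heights so the lowest point is zero
#'
#' Subtracts the minimum z from every point; idempotent.
#'
#' @param cloud n x 3 matrix.
#' @return The cloud with `min(z) == 0` (empty clouds pass through).
#' @export
normalize_heights <- function(cloud) {
  cloud <- as_cloud(cloud)
  if (nrow(cloud) == 0) return(cloud)
  cloud[, 3] <- cloud[, 3] - min(cloud[, 3])
  cloud
}

#' Clip a cloud to the seedbed bounds
#'
#' Manual axis-aligned delimitation keeping only the data above the seedbed
#' under study. Bounds are inclusive; `NULL` leaves that axis unclipped.
#'
#' @param cloud n x 3 matrix.
#' @param x_bounds,y_bounds Length-2 numeric vectors (mm) or `NULL`.
#' @return The retained points.
#' @export
delimit_seedbed <- function(cloud, x_bounds = NULL, y_bounds = NULL) {
  cloud <- as_cloud(cloud)
  for (b in list(x_bounds, y_bounds)) {
    if (!is.null(b) && (length(b) != 2 || b[1] > b[2])) {
      rs_invalid("bounds must be length-2 with lower <= upper")
    }
  }
  keep <- rep(TRUE, nrow(cloud))
  if (!is.null(x_bounds)) keep <- keep & cloud[, 1] >= x_bounds[1] & cloud[, 1] <= x_bounds[2]
  if (!is.null(y_bounds)) keep <- keep & cloud[, 2] >= y_bounds[1] & cloud[, 2] <= y_bounds[2]
  cloud[keep, , drop = FALSE]
}

#' Box-grid downsampling
#'
#' Partitions space into cubic boxes of edge `grid_step_mm`, anchored at the
#' minimum corner of the cloud; every occupied box contributes the centroid
#' of its points. Never increases the point count and leaves already-sparse
#' clouds unchanged.
#'
#' @param cloud n x 3 matrix.
#' @param config A [lidar_config()] (its `grid_step_mm` is used), or a
#'   single number giving the step directly.
#' @return The downsampled cloud.
#' @export
grid_downsample <- function(cloud, config) {
  step <- if (is.numeric(config)) config else config$grid_step_mm
  if (!is.finite(step) || step <= 0) rs_invalid("grid step must be > 0")
  cloud <- as_cloud(cloud)
  if (nrow(cloud) <= 1) return(cloud)
  anchor <- apply(cloud, 2, min)
  idx <- floor(sweep(cloud, 2, anchor) / step)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = "_")
  sums <- rowsum(cloud, key, reorder = FALSE)
  n <- as.vector(table(factor(key, levels = rownames(sums))))
  out <- sums / n
  colnames(out) <- c("x", "y", "z")
  rownames(out) <- NULL
  out
}
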