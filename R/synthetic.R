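# Synthetic row and sensor-log generators. The simulated world is a raised
# trapezoidal seedbed carrying one row of plants (or calibration sticks),
# traversed at constant speed by a platform carrying a ground-wheel encoder,
# a low light-beam, a side-view LiDAR and a side-view camera.
#
# Platform frame: x = travel direction, y = lateral distance from the
# sensor, z = up, with z = 0 at the furrow floor. The LiDAR sits at
# (x = Enc, 0, sensor_height_mm) and scans in the plane x' = 0 of its own
# frame; angle 0 points along +y' and positive angles point down toward the
# bed, so that the side-view pose (roll 0, pitch -180, yaw 0, Enc) maps its
# points back into the platform frame.
#
# Each generator draws from an RNG stream derived from sim_config$seed plus
# a fixed per-generator offset, so outputs are reproducible and independent
# of call order.

bed_top_z <- function(cfg, x) cfg$bed_height_mm + cfg$bed_tilt * x

plant_height <- function(cfg) {
  if (cfg$shape == "stick") cfg$stick_height_mm else cfg$stem_height_mm
}

plant_radius <- function(cfg) {
  (if (cfg$shape == "stick") cfg$stick_diameter_mm else cfg$stem_diameter_mm) / 2
}

#' Lateral seedbed bounds of the simulated world
#'
#' The y interval covered by the seedbed top, suitable as the `y_bounds`
#' seedbed delimitation of a [lidar_config()] when processing simulated
#' scans.
#'
#' @param cfg A [sim_config()].
#' @return Length-2 numeric vector (mm).
#' @export
sim_seedbed_bounds <- function(cfg) {
  c(cfg$sensor_offset_mm - cfg$bed_width_mm / 2,
    cfg$sensor_offset_mm + cfg$bed_width_mm / 2)
}

#' Generate ground-truth plant positions
#'
#' Positions are cumulative sums of the nominal spacing plus Gaussian
#' jitter (transplanting was intentionally non-uniform), offset by the row
#' margin. Plants may drop out with `missing_prob`; planned positions of
#' dropped plants are recorded in the `dropped` attribute.
#'
#' @param cfg A [sim_config()].
#' @return A [row_truth()].
#' @export
gen_row_truth <- function(cfg) {
  set.seed(cfg$seed)
  if (cfg$n_plants == 0) {
    truth <- row_truth(numeric(0), character(0))
    attr(truth, "dropped") <- numeric(0)
    return(truth)
  }
  gaps <- cfg$spacing_mm + stats::rnorm(cfg$n_plants - 1, 0, cfg$spacing_jitter_mm)
  gaps <- pmax(gaps, 1)
  pos <- cfg$row_margin_mm + cumsum(c(0, gaps))
  keep <- stats::runif(cfg$n_plants) >= cfg$missing_prob
  labels <- sprintf("%s%02d", if (cfg$shape == "stick") "S" else "P",
                    seq_len(cfg$n_plants))
  truth <- row_truth(pos[keep], labels[keep])
  attr(truth, "dropped") <- pos[!keep]
  truth
}

#' Generate a light-beam / encoder log
#'
#' Samples the beam state at every encoder pulse. The beam runs at stem
#' height, so it is blocked where it crosses a stem cylinder; the TTL state
#' is held for one pulse on each side of the geometric interruption
#' (sensor latching), so a stem of width w produces a blocked run of
#' length in (w, w + 2 pulse distances]. Optional spurious sub-4-mm blips
#' (weeds, leaves) are added per inter-plant gap with `weed_prob`.
#'
#' @param truth A [row_truth()].
#' @param cfg A [sim_config()].
#' @return A [beam_log()] with one record per encoder pulse.
#' @export
gen_beam_log <- function(truth, cfg) {
  set.seed(cfg$seed + 1L)
  rel <- cfg$pulse_mm
  total <- (if (length(truth$positions)) max(truth$positions) else 0) + cfg$row_margin_mm
  n_pulse <- ceiling(total / rel)
  p <- 0:n_pulse
  state <- integer(n_pulse + 1)

  mark <- function(lo_mm, hi_mm, latch = TRUE) {
    pad <- if (latch) rel else 0
    lo <- max(0, ceiling((lo_mm - pad) / rel))
    hi <- min(n_pulse, floor((hi_mm + pad) / rel))
    if (hi >= lo) state[(lo:hi) + 1] <<- 1L
  }

  r <- plant_radius(cfg)
  for (xp in truth$positions) mark(xp - r, xp + r)
  if (cfg$weed_prob > 0 && length(truth$positions) > 1) {
    for (i in seq_len(length(truth$positions) - 1)) {
      if (stats::runif(1) < cfg$weed_prob) {
        gap <- c(truth$positions[i] + r + 10, truth$positions[i + 1] - r - 10)
        if (diff(gap) > 20) {
          centre <- stats::runif(1, gap[1], gap[2])
          width <- stats::runif(1, 0.5, 1.2)
          mark(centre - width / 2, centre + width / 2, latch = FALSE)
        }
      }
    }
  }
  beam_log(p, state, timestamp_ms = p * rel / cfg$speed_mm_s * 1000)
}

# Ray-cast one scan at along-track position xs. ca/sa are cos/sin of the
# beam angles; returns a range per beam (0 = no return).
cast_scan <- function(cfg, truth, xs, ca, sa) {
  hs <- cfg$sensor_height_mm
  yb <- sim_seedbed_bounds(cfg)
  zb <- bed_top_z(cfg, xs)
  t_best <- rep(Inf, length(ca))

  down <- sa > 1e-9
  # seedbed top
  t <- ifelse(down, (hs - zb) / sa, Inf)
  y <- t * ca
  hit <- down & y >= yb[1] & y <= yb[2]
  t_best[hit] <- pmin(t_best[hit], t[hit])
  # furrow floor, near side and far side (far side only when the beam
  # clears the bed-top edge; bed flanks absorb, no flank returns)
  tf <- ifelse(down, hs / sa, Inf)
  yf <- tf * ca
  v_edge <- ifelse(ca > 1e-9, yb[2] * sa / ca, Inf)
  hit <- down & (yf < yb[1] | (yf > yb[2] & yf <= yb[2] + 600 & v_edge < hs - zb))
  t_best[hit] <- pmin(t_best[hit], tf[hit])

  r <- plant_radius(cfg)
  h <- plant_height(cfg)
  for (xp in truth$positions) {
    dx <- xs - xp
    if (abs(dx) < r) {
      w <- sqrt(r^2 - dx^2)
      ys <- cfg$sensor_offset_mm - w
      t <- ifelse(ca > 1e-9, ys / ca, Inf)
      zhit <- hs - t * sa
      hit <- is.finite(t) & t > 0 & zhit >= zb & zhit <= zb + h
      t_best[hit] <- pmin(t_best[hit], t[hit])
    }
    if (cfg$shape == "tomato") {
      cx <- xp + cfg$foliage_lean_mm
      dxf <- xs - cx
      if (abs(dxf) < cfg$foliage_radius_mm) {
        sc <- sqrt(1 - (dxf / cfg$foliage_radius_mm)^2)
        be <- cfg$foliage_radius_mm * sc
        ce <- cfg$foliage_height_mm * sc
        zc <- zb + cfg$stem_height_mm
        u <- ca / be; p0 <- -cfg$sensor_offset_mm / be
        v <- -sa / ce; q0 <- (hs - zc) / ce
        qa <- u^2 + v^2
        qb <- 2 * (u * p0 + v * q0)
        qc <- p0^2 + q0^2 - 1
        disc <- qb^2 - 4 * qa * qc
        ok <- disc >= 0
        t <- ifelse(ok, (-qb - sqrt(pmax(disc, 0))) / (2 * qa), Inf)
        hit <- ok & t > 0
        t_best[hit] <- pmin(t_best[hit], t[hit])
      }
    }
  }
  ifelse(is.finite(t_best) & t_best <= 20000, t_best, 0)
}

#' Generate side-view LiDAR scans of a row
#'
#' Advances the platform at constant speed, emitting one scan per scan
#' period with beams at the configured angular resolution over the
#' simulated field of view. Each beam returns the range to the nearest
#' surface (seedbed top, furrow floor, stem cylinder, foliage shell) plus
#' Gaussian range noise; beams hitting nothing return 0. The encoder value
#' recorded with each scan is quantized to the pulse distance.
#'
#' @param truth A [row_truth()].
#' @param cfg A [sim_config()].
#' @return A [scan_set()].
#' @export
gen_lidar_scans <- function(truth, cfg) {
  set.seed(cfg$seed + 2L)
  total <- (if (length(truth$positions)) max(truth$positions) else 0) + cfg$row_margin_mm
  times <- seq(0, total / cfg$speed_mm_s, by = 1 / cfg$scan_hz)
  angles <- seq(cfg$fov_deg[1], cfg$fov_deg[2], by = cfg$angular_res_deg)
  ca <- cospi(angles / 180); sa <- sinpi(angles / 180)
  n_a <- length(angles)

  ranges <- numeric(length(times) * n_a)
  for (i in seq_along(times)) {
    xs <- cfg$speed_mm_s * times[i]
    rr <- cast_scan(cfg, truth, xs, ca, sa)
    got <- rr > 0
    rr[got] <- pmax(rr[got] + stats::rnorm(sum(got), 0, cfg$noise_mm), 0)
    ranges[(i - 1) * n_a + seq_len(n_a)] <- rr
  }
  enc <- round(cfg$speed_mm_s * times / cfg$pulse_mm) * cfg$pulse_mm
  scan_set(
    scan_id = rep(seq_along(times), each = n_a),
    timestamp_ms = rep(times * 1000, each = n_a),
    encoder_mm = rep(enc, each = n_a),
    angle_deg = rep(angles, length(times)),
    range_mm = ranges
  )
}

#' Generate side-view camera frame metadata
#'
#' One frame per shooting interval of simulated travel. The encoder value
#' corresponds to the image centre; every plant whose stem falls inside
#' the frame contributes an observation with its exact signed pixel offset
#' (positive toward larger along-track positions) from the pinhole
#' side-view model at the configured image scale. Frames without a visible
#' stem carry one record with an NA offset.
#'
#' @param truth A [row_truth()].
#' @param cfg A [sim_config()].
#' @param offset_noise_px Standard deviation of optional Gaussian pixel
#'   noise on the offsets (default 0: exact).
#' @return A data.frame of class `frame_meta` with columns `frame_id`,
#'   `timestamp_ms`, `encoder_mm`, `stem_offset_px`.
#' @export
gen_frames <- function(truth, cfg, offset_noise_px = 0) {
  set.seed(cfg$seed + 3L)
  total <- (if (length(truth$positions)) max(truth$positions) else 0) + cfg$row_margin_mm
  times <- seq(0, total / cfg$speed_mm_s, by = cfg$frame_interval_s)
  enc <- round(cfg$speed_mm_s * times / cfg$pulse_mm) * cfg$pulse_mm
  half_px <- cfg$frame_width_px / 2

  rows <- lapply(seq_along(times), function(i) {
    off <- (truth$positions - enc[i]) / cfg$mm_per_px
    off <- off[abs(off) <= half_px]
    if (length(off) == 0) off <- NA_real_
    else if (offset_noise_px > 0) off <- off + stats::rnorm(length(off), 0, offset_noise_px)
    data.frame(frame_id = i, timestamp_ms = times[i] * 1000,
               encoder_mm = enc[i], stem_offset_px = off)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("frame_meta", "data.frame")
  out
}

#' Render one synthetic side-view frame
#'
#' Draws the world seen at a given encoder value: textured soil background
#' (the texture is a function of the world coordinate, so consecutive
#' frames are exact translations of each other) with each visible plant as
#' a dark-green stem and a green foliage disc. Intended for exercising the
#' segmentation and registration functions; not radiometrically realistic.
#'
#' @param truth A [row_truth()].
#' @param cfg A [sim_config()].
#' @param encoder_mm Along-track position of the image centre (mm).
#' @param width_px,height_px Rendered size in pixels.
#' @param mm_per_px Image scale; defaults to the configured one.
#' @return `height_px x width_px x 3` numeric array in \[0, 1\].
#' @export
render_frame <- function(truth, cfg, encoder_mm, width_px = 240,
                         height_px = 160, mm_per_px = cfg$mm_per_px) {
  wx <- encoder_mm + (seq_len(width_px) - (width_px + 1) / 2) * mm_per_px
  texture <- 0.06 * sin(wx * 0.21) + 0.05 * sin(wx * 0.047) + 0.03 * sin(wx * 1.31)
  img <- array(0, dim = c(height_px, width_px, 3))
  img[, , 1] <- matrix(0.45 + texture, height_px, width_px, byrow = TRUE)
  img[, , 2] <- matrix(0.33 + texture, height_px, width_px, byrow = TRUE)
  img[, , 3] <- matrix(0.20 + 0.5 * texture, height_px, width_px, byrow = TRUE)

  soil_row <- round(0.9 * height_px)
  top_row <- round(0.35 * height_px)
  disc_r <- max(3, round(0.12 * height_px))
  rr <- matrix(seq_len(height_px), height_px, width_px)
  for (xp in truth$positions) {
    cols <- which(abs(wx - xp) <= plant_radius(cfg) * 1.5)
    if (length(cols)) {
      for (ch in 1:3) {
        img[top_row:soil_row, cols, ch] <- c(0.10, 0.45, 0.10)[ch]
      }
    }
    ctr_col <- which.min(abs(wx - xp))
    if (abs(wx[ctr_col] - xp) < mm_per_px && cfg$shape == "tomato") {
      cc <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
      disc <- (rr - top_row)^2 + (cc - ctr_col)^2 <= disc_r^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[disc] <- c(0.12, 0.55, 0.12)[ch]
        img[, , ch] <- plane
      }
    }
  }
  pmin(pmax(img, 0), 1)
}
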